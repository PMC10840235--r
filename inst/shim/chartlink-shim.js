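/* chartlink browser shim.
 *
 * Single static script served with every page. Opens the message channel,
 * forwards DOM events on elements whose identifiers match the shared
 * grammar ("lc-{chart}-{layer}-{index}" / "lc-{chart}-{layer}-{row}-{col}"),
 * applies whole-fragment replacements sent by the server, and forwards
 * input-widget changes. Stateless beyond a bounded send queue: reloading
 * the page yields a fresh working session.
 *
 * Wire protocol: one JSON text frame per message, {kind, token, body}.
 */
(function () {
  "use strict";

  var MAX_QUEUE = 100;
  var HOVER_MIN_SPACING_MS = 50;

  /* Pure parse function for the identifier grammar; heatmap cells carry two
   * trailing indices (row, col), everything else one. Returns null for
   * non-matching ids. Indices are 0-based on the wire. */
  function parseElementId(id) {
    if (typeof id !== "string") return null;
    var m = /^lc-([A-Za-z0-9_.]+)-(L\d+)-(\d+)(?:-(\d+))?$/.exec(id);
    if (!m) return null;
    var payload = m[4] === undefined
      ? parseInt(m[3], 10)
      : [parseInt(m[3], 10), parseInt(m[4], 10)];
    return { chart_id: m[1], layer_id: m[2], payload: payload };
  }

  function widgetState(el) {
    if (el.type === "checkbox") {
      var group = document.getElementsByName(el.name);
      var states = [];
      for (var i = 0; i < group.length; i++) states.push(group[i].checked);
      return states;
    }
    if (el.type === "radio") {
      var radios = document.getElementsByName(el.name);
      for (var j = 0; j < radios.length; j++) {
        if (radios[j].checked) return j + 1; /* 1-based selected index */
      }
      return null;
    }
    if (el.type === "range") return parseFloat(el.value);
    return el.value;
  }

  var cfg = window.CHARTLINK || { endpoint: "/ws" };
  var token = null;
  var queue = [];
  var lastHover = 0;
  var ws = null;

  function send(kind, body) {
    var frame = JSON.stringify({ kind: kind, token: token || "", body: body });
    if (ws && ws.readyState === 1 && token !== null) {
      ws.send(frame);
    } else {
      queue.push(frame);
      if (queue.length > MAX_QUEUE) queue.shift(); /* drop oldest */
    }
  }

  function flushQueue() {
    while (queue.length && ws && ws.readyState === 1 && token !== null) {
      /* re-stamp queued frames with the (possibly late) token */
      var f = JSON.parse(queue.shift());
      f.token = token;
      ws.send(JSON.stringify(f));
    }
  }

  function applyUpdate(body) {
    var container = document.getElementById(body.container);
    if (!container) {
      console.warn("chartlink: update for unknown container", body.container);
      return;
    }
    container.innerHTML = body.markup;
    /* listeners use event delegation on the document: nothing to re-attach */
  }

  function onFrame(text) {
    var msg;
    try { msg = JSON.parse(text); } catch (e) {
      console.warn("chartlink: unparseable frame"); return;
    }
    if (msg.kind === "hello") { token = msg.token; flushQueue(); }
    else if (msg.kind === "update") applyUpdate(msg.body);
    else if (msg.kind === "error") console.warn("chartlink server:", msg.body.message);
    else if (msg.kind === "bye") { if (ws) ws.close(); }
  }

  function forwardEvent(eventType, domEvent) {
    var parsed = parseElementId(domEvent.target && domEvent.target.id);
    if (!parsed) return; /* background and non-chart elements are ignored */
    if (eventType === "hover") {
      var now = Date.now();
      if (now - lastHover < HOVER_MIN_SPACING_MS) return;
      lastHover = now;
    }
    send("event", {
      chart_id: parsed.chart_id,
      layer_id: parsed.layer_id,
      event_type: eventType,
      payload: parsed.payload
    });
  }

  function forwardInput(domEvent) {
    var el = domEvent.target;
    if (!el || !el.getAttribute || !el.getAttribute("data-lc-widget")) return;
    send("event", {
      chart_id: el.getAttribute("data-lc-widget"),
      layer_id: "L0",
      event_type: "input_change",
      payload: widgetState(el)
    });
  }

  function connect() {
    var proto = location.protocol === "https:" ? "wss://" : "ws://";
    ws = new WebSocket(proto + location.host + cfg.endpoint);
    ws.onmessage = function (ev) { onFrame(ev.data); };
    ws.onopen = flushQueue;
  }

  /* Event delegation on the document root, filtered by the "lc-" prefix, so
   * fragment replacement never orphans listeners. */
  document.addEventListener("click", function (ev) { forwardEvent("click", ev); });
  document.addEventListener("mouseover", function (ev) { forwardEvent("hover", ev); });
  document.addEventListener("change", forwardInput);

  if (typeof WebSocket !== "undefined" && !cfg.headless) connect();

  /* exported for headless contract tests */
  window.chartlinkShim = { parseElementId: parseElementId, widgetState: widgetState };
})();
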