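#' Write a PTA-net to PNML
#'
#' Serialises the net in PNML (Petri Net Markup Language, 2009 grammar,
#' place/transition net type).  Weighted arcs carry their weight as an
#' `<inscription>`; initial markings as `<initialMarking>`.  Activator
#' arcs are not part of the PT-net grammar and are encoded as arcs with a
#' tool-specific annotation
#' `<toolspecific tool="petrigrad" version="1.0"><arctype>activator</arctype></toolspecific>`,
#' which [read_pnml()] recognises; other tools will render them as plain
#' arcs.
#'
#' @param net a `pta_net`.
#' @param path output file path.
#' @param name_map optional named character vector mapping identifiers to
#'   human-readable `<name>` labels.
#' @return invisibly, `path`.
#' @export
write_pnml <- function(net, path, name_map = NULL) {
  doc <- xml2::xml_new_root("pnml",
                            xmlns = "http://www.pnml.org/version-2009/grammar/pnml")
  netnode <- xml2::xml_add_child(doc, "net", id = "net1",
    type = "http://www.pnml.org/version-2009/grammar/ptnet")
  page <- xml2::xml_add_child(netnode, "page", id = "page1")
  add_text <- function(parent, tag, text) {
    node <- xml2::xml_add_child(parent, tag)
    xml2::xml_add_child(node, "text", text)
    node
  }
  for (p in net$places) {
    pn <- xml2::xml_add_child(page, "place", id = p)
    if (!is.null(name_map) && p %in% names(name_map))
      add_text(pn, "name", name_map[[p]])
    if (net$m0[p] > 0)
      add_text(pn, "initialMarking", format(net$m0[p], scientific = FALSE))
  }
  for (t in net$transitions) {
    tn <- xml2::xml_add_child(page, "transition", id = t)
    if (!is.null(name_map) && t %in% names(name_map))
      add_text(tn, "name", name_map[[t]])
  }
  aid <- 0L
  add_arc <- function(src, tgt, w, activator = FALSE) {
    aid <<- aid + 1L
    an <- xml2::xml_add_child(page, "arc", id = paste0("a", aid),
                              source = src, target = tgt)
    if (w > 1) add_text(an, "inscription", format(w, scientific = FALSE))
    if (activator) {
      ts <- xml2::xml_add_child(an, "toolspecific", tool = "petrigrad",
                                version = "1.0")
      xml2::xml_add_child(ts, "arctype", "activator")
    }
    invisible(NULL)
  }
  for (t in net$transitions) {
    for (p in net$places[net$pre[, t] > 0]) add_arc(p, t, net$pre[p, t])
    for (p in net$places[net$post[, t] > 0]) add_arc(t, p, net$post[p, t])
    for (p in net$places[net$act[, t]]) add_arc(p, t, 1, activator = TRUE)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a PTA-net from PNML
#'
#' Reads a place/transition PNML file written by [write_pnml()] (or any
#' PT-net PNML with integer inscriptions).  Arcs annotated with the
#' tool-specific `arctype` "activator" become activator arcs.
#'
#' @param path PNML file path.
#' @return a `pta_net`.
#' @export
read_pnml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "p")
  places <- xml2::xml_find_all(doc, ".//p:place", ns)
  transitions <- xml2::xml_find_all(doc, ".//p:transition", ns)
  arcs <- xml2::xml_find_all(doc, ".//p:arc", ns)
  pid <- xml2::xml_attr(places, "id")
  tid <- xml2::xml_attr(transitions, "id")
  mk <- vapply(places, function(pn) {
    node <- xml2::xml_find_first(pn, "./p:initialMarking/p:text", ns)
    if (inherits(node, "xml_missing")) 0 else as.numeric(xml2::xml_text(node))
  }, 0)
  src <- xml2::xml_attr(arcs, "source")
  tgt <- xml2::xml_attr(arcs, "target")
  w <- vapply(arcs, function(an) {
    node <- xml2::xml_find_first(an, "./p:inscription/p:text", ns)
    if (inherits(node, "xml_missing")) 1 else as.numeric(xml2::xml_text(node))
  }, 0)
  is_act <- vapply(arcs, function(an) {
    node <- xml2::xml_find_first(
      an, "./p:toolspecific[@tool='petrigrad']/p:arctype", ns)
    !inherits(node, "xml_missing") && xml2::xml_text(node) == "activator"
  }, FALSE)
  activators <- NULL
  if (any(is_act))
    activators <- data.frame(place = src[is_act], transition = tgt[is_act])
  arcs_df <- data.frame(from = src[!is_act], to = tgt[!is_act],
                        weight = w[!is_act])
  m0 <- stats::setNames(mk, pid)
  pta_net(places = pid, transitions = tid, arcs = arcs_df,
          activators = activators, m0 = m0[m0 > 0])
}
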