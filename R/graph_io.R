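#' Write a trait graph to GraphML or JSON
#'
#' GraphML carries node attributes `code`, `intensity`, `state`, edge
#' attribute `weight` and graph attributes `owner_id`, `epsilon`, `mode`
#' and the trait order; the JSON dialect carries the same fields.  Both
#' round-trip losslessly (numeric fields written at full double
#' precision).  The format is inferred from the file extension
#' (`.graphml` / `.json`) unless given explicitly.
#'
#' @param g a `pgk_graph`.
#' @param path destination file.
#' @param format `"graphml"` or `"json"`; default inferred from `path`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("auto", "graphml", "json")) {
  stopifnot(inherits(g, "pgk_graph"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "graphml"
  if (format == "json") {
    jsonlite::write_json(
      list(owner_id = g$owner_id, mode = g$mode, epsilon = g$epsilon,
           traits = g$codes,
           nodes = data.frame(code = g$codes,
                              intensity = unname(g$intensity),
                              state = unname(g$state),
                              stringsAsFactors = FALSE),
           edges = g$edges),
      path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  num <- function(x) sprintf("%.17g", x)
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (k in list(c("d_code", "node", "code", "string"),
                 c("d_int", "node", "intensity", "double"),
                 c("d_state", "node", "state", "string"),
                 c("d_w", "edge", "weight", "double"),
                 c("d_owner", "graph", "owner_id", "string"),
                 c("d_eps", "graph", "epsilon", "double"),
                 c("d_mode", "graph", "mode", "string"),
                 c("d_traits", "graph", "traits", "string")))
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = k[4])
  gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  add_data <- function(node, key, value) {
    d <- xml2::xml_add_child(node, "data", key = key)
    xml2::xml_text(d) <- as.character(value)
  }
  add_data(gr, "d_owner", g$owner_id)
  add_data(gr, "d_eps", num(g$epsilon))
  add_data(gr, "d_mode", g$mode)
  add_data(gr, "d_traits", paste(g$codes, collapse = ","))
  for (i in seq_along(g$codes)) {
    n <- xml2::xml_add_child(gr, "node", id = g$codes[i])
    add_data(n, "d_code", g$codes[i])
    add_data(n, "d_int", num(g$intensity[i]))
    add_data(n, "d_state", g$state[i])
  }
  if (nrow(g$edges))
    for (i in seq_len(nrow(g$edges))) {
      e <- xml2::xml_add_child(gr, "edge",
                               source = g$edges$a[i], target = g$edges$b[i])
      add_data(e, "d_w", num(g$edges$weight[i]))
    }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a trait graph written by [write_graph_file()]
#'
#' @param path source file (`.graphml` or `.json`).
#' @param format format override.
#' @return A `pgk_graph`.
#' @export
read_graph_file <- function(path, format = c("auto", "graphml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "graphml"
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    codes <- as.character(obj$traits)
    nodes <- as.data.frame(obj$nodes)
    return(.assemble_graph(path, codes, nodes,
                           if (length(obj$edges)) as.data.frame(obj$edges)
                           else data.frame(a = character(), b = character(),
                                           weight = numeric()),
                           obj$owner_id, obj$epsilon, obj$mode))
  }
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed GraphML file '", path,
                                           "': ", conditionMessage(e)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  gdata <- function(node, key) {
    d <- xml2::xml_find_first(node, sprintf("./g:data[@key='%s']", key), ns)
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  gr <- xml2::xml_find_first(doc, ".//g:graph", ns)
  if (inherits(gr, "xml_missing"))
    stop("malformed GraphML file '", path, "': no <graph> element")
  codes <- strsplit(gdata(gr, "d_traits"), ",", fixed = TRUE)[[1L]]
  node_els <- xml2::xml_find_all(gr, "./g:node", ns)
  nodes <- data.frame(
    code = vapply(node_els, gdata, character(1), key = "d_code"),
    intensity = as.numeric(vapply(node_els, gdata, character(1), key = "d_int")),
    state = vapply(node_els, gdata, character(1), key = "d_state"),
    stringsAsFactors = FALSE)
  edge_els <- xml2::xml_find_all(gr, "./g:edge", ns)
  edges <- data.frame(
    a = xml2::xml_attr(edge_els, "source"),
    b = xml2::xml_attr(edge_els, "target"),
    weight = as.numeric(vapply(edge_els, gdata, character(1), key = "d_w")),
    stringsAsFactors = FALSE)
  .assemble_graph(path, codes, nodes, edges,
                  gdata(gr, "d_owner"),
                  as.numeric(gdata(gr, "d_eps")),
                  gdata(gr, "d_mode"))
}

.assemble_graph <- function(path, codes, nodes, edges, owner, epsilon, mode) {
  miss <- setdiff(codes, nodes$code)
  if (length(miss))
    stop("graph file '", path, "' is missing a node entry for trait '",
         miss[1L], "'")
  if (anyNA(nodes$intensity))
    stop("graph file '", path, "' has a non-numeric node intensity")
  ord <- match(codes, nodes$code)
  structure(list(owner_id = owner,
                 codes = codes,
                 intensity = stats::setNames(nodes$intensity[ord], codes),
                 state = stats::setNames(nodes$state[ord], codes),
                 edges = edges,
                 epsilon = epsilon,
                 mode = mode),
            class = "pgk_graph")
}
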