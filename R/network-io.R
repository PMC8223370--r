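#' Convert an interval network to igraph
#'
#' @param network An `interval_network`.
#' @return An undirected [igraph::igraph] with node attributes
#'   `change_status`, `p_baseline` and edge attributes `r`, `sign`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "interval_network"))
  igraph::graph_from_data_frame(
    network$edges[c("from", "to", "r", "sign")], directed = FALSE,
    vertices = network$nodes[c("mediator", "change_status", "p_baseline")])
}

# shortest decimal representation that parses back to the identical double,
# so text files stay human-readable and round-trip exactly
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, "")
}

#' Write an interval network to disk
#'
#' Two formats are supported.  `"edgelist"` is a tab-separated file with the
#' header `source  target  sign  r` and one line per edge; network metadata
#' and per-node change status travel in `#`-prefixed comment lines so the
#' file round-trips losslessly.  The sign is stored as an explicit `+`/`-`
#' character so it survives any rounding of `r` in downstream text handling.
#' `"graphml"` is standard GraphML with node attributes `change_status`,
#' `p_baseline` and edge attributes `sign`, `r`.  Numbers are written at
#' full double precision in both formats, so [read_network()] reproduces the
#' network exactly.
#'
#' @param network An `interval_network`.
#' @param path Output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @seealso [read_network()]
#' @export
write_network <- function(network, path, format = c("edgelist", "graphml")) {
  stopifnot(inherits(network, "interval_network"))
  format <- match.arg(format)
  if (format == "edgelist") write_network_edgelist(network, path)
  else write_network_graphml(network, path)
  invisible(path)
}

write_network_edgelist <- function(network, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(
    "# dynanet interval network v1",
    paste0("# strain\t", network$strain),
    paste0("# compartment\t", network$compartment),
    paste0("# interval\t", fmt_num(network$interval[1]), "\t",
           fmt_num(network$interval[2])),
    paste0("# threshold\t", fmt_num(network$threshold)),
    paste0("# alpha\t", fmt_num(network$alpha)),
    paste0("# node\t", network$nodes$mediator, "\t",
           network$nodes$change_status, "\t",
           fmt_num(network$nodes$p_baseline)))
  writeLines(meta, con)
  writeLines("source\ttarget\tsign\tr", con)
  if (nrow(network$edges))
    writeLines(paste(network$edges$from, network$edges$to,
                     network$edges$sign, fmt_num(network$edges$r),
                     sep = "\t"), con)
}

write_network_graphml <- function(network, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c("g_strain", "graph", "strain", "string"),
    c("g_compartment", "graph", "compartment", "string"),
    c("g_start_h", "graph", "start_h", "double"),
    c("g_end_h", "graph", "end_h", "double"),
    c("g_threshold", "graph", "threshold", "double"),
    c("g_alpha", "graph", "alpha", "double"),
    c("v_change_status", "node", "change_status", "string"),
    c("v_p_baseline", "node", "p_baseline", "double"),
    c("e_sign", "edge", "sign", "string"),
    c("e_r", "edge", "r", "double"))
  for (k in keys)
    xml2::xml_add_child(doc, "key", id = k[1], "for" = k[2],
                        "attr.name" = k[3], "attr.type" = k[4])
  g <- xml2::xml_add_child(doc, "graph", id = "dyna",
                           edgedefault = "undirected")
  gdata <- c(strain = network$strain, compartment = network$compartment,
             start_h = fmt_num(network$interval[1]),
             end_h = fmt_num(network$interval[2]),
             threshold = fmt_num(network$threshold),
             alpha = fmt_num(network$alpha))
  for (nm in names(gdata))
    xml2::xml_add_child(g, "data", key = paste0("g_", nm), gdata[[nm]])
  for (i in seq_len(nrow(network$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = network$nodes$mediator[i])
    xml2::xml_add_child(nd, "data", key = "v_change_status",
                        network$nodes$change_status[i])
    xml2::xml_add_child(nd, "data", key = "v_p_baseline",
                        fmt_num(network$nodes$p_baseline[i]))
  }
  for (i in seq_len(nrow(network$edges))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = network$edges$from[i],
                              target = network$edges$to[i])
    xml2::xml_add_child(ed, "data", key = "e_sign", network$edges$sign[i])
    xml2::xml_add_child(ed, "data", key = "e_r",
                        fmt_num(network$edges$r[i]))
  }
  xml2::write_xml(doc, path)
}

#' Read an interval network written by [write_network()]
#'
#' @param path File path.
#' @param format `"edgelist"` or `"graphml"`; default guesses from the file
#'   extension.
#' @return An `interval_network`.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "edgelist"
  if (format == "edgelist") read_network_edgelist(path)
  else read_network_graphml(path)
}

assemble_network <- function(strain, compartment, interval, threshold,
                             alpha, mediator, change_status, p_baseline,
                             edges) {
  degree <- stats::setNames(integer(length(mediator)), mediator)
  if (nrow(edges)) {
    tab <- table(c(edges$from, edges$to))
    degree[names(tab)] <- as.integer(tab)
  }
  nodes <- data.frame(mediator = mediator, p_baseline = p_baseline,
                      changed = change_status != "unchanged",
                      degree = as.integer(degree),
                      change_status = change_status, row.names = NULL)
  structure(
    list(strain = strain, compartment = compartment, interval = interval,
         threshold = threshold, alpha = alpha, nodes = nodes,
         edges = edges,
         skipped = data.frame(mediator_a = character(),
                              mediator_b = character(),
                              reason = character())),
    class = "interval_network")
}

read_network_edgelist <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  comments <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(sub("^# ", "", comments), "\t", fixed = TRUE)
  get1 <- function(key) {
    hit <- Filter(function(f) f[1] == key, fields)
    if (!length(hit)) stop("edge-list file lacks '", key, "' metadata",
                           call. = FALSE)
    hit[[1]][-1]
  }
  node_rows <- Filter(function(f) f[1] == "node", fields)
  if (!length(node_rows))
    stop("edge-list file lacks node metadata lines", call. = FALSE)
  mediator <- vapply(node_rows, `[`, "", 2L)
  change_status <- vapply(node_rows, `[`, "", 3L)
  p_baseline <- as.numeric(vapply(node_rows, `[`, "", 4L))

  if (!length(body) || body[1] != "source\ttarget\tsign\tr")
    stop("edge-list file lacks the 'source target sign r' header",
         call. = FALSE)
  body <- body[-1]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[`, "", 1L),
      to = vapply(parts, `[`, "", 2L),
      r = as.numeric(vapply(parts, `[`, "", 4L)),
      sign = vapply(parts, `[`, "", 3L))
  } else {
    edges <- data.frame(from = character(), to = character(),
                        r = numeric(), sign = character())
  }
  assemble_network(
    strain = get1("strain"), compartment = get1("compartment"),
    interval = as.numeric(get1("interval")),
    threshold = as.numeric(get1("threshold")),
    alpha = as.numeric(get1("alpha")),
    mediator = mediator, change_status = change_status,
    p_baseline = p_baseline, edges = edges)
}

read_network_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  g <- xml2::xml_find_first(doc, ".//graph")
  gdata <- function(key) {
    nd <- xml2::xml_find_first(
      g, sprintf("./data[@key='g_%s']", key))
    xml2::xml_text(nd)
  }
  nodes <- xml2::xml_find_all(g, "./node")
  mediator <- xml2::xml_attr(nodes, "id")
  nfield <- function(nd, key)
    xml2::xml_text(xml2::xml_find_first(
      nd, sprintf("./data[@key='%s']", key)))
  change_status <- vapply(nodes, nfield, "", "v_change_status")
  p_baseline <- as.numeric(vapply(nodes, nfield, "", "v_p_baseline"))
  enodes <- xml2::xml_find_all(g, "./edge")
  if (length(enodes)) {
    edges <- data.frame(
      from = xml2::xml_attr(enodes, "source"),
      to = xml2::xml_attr(enodes, "target"),
      r = as.numeric(vapply(enodes, nfield, "", "e_r")),
      sign = vapply(enodes, nfield, "", "e_sign"))
  } else {
    edges <- data.frame(from = character(), to = character(),
                        r = numeric(), sign = character())
  }
  assemble_network(
    strain = gdata("strain"), compartment = gdata("compartment"),
    interval = c(as.numeric(gdata("start_h")),
                 as.numeric(gdata("end_h"))),
    threshold = as.numeric(gdata("threshold")),
    alpha = as.numeric(gdata("alpha")),
    mediator = mediator, change_status = change_status,
    p_baseline = p_baseline, edges = edges)
}
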