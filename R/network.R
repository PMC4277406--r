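#' Build the bipartite enrichment network
#'
#' Summarises a classification as a graph connecting enriched-set nodes to
#' tissue nodes: one *tissue_enriched* node per tissue that has at least
#' one (highly or moderately) tissue-enriched gene, and one
#' *group_enriched* node per distinct enriched tissue group. Each set node
#' is connected to every tissue in its defining set. Group nodes are kept
#' only when they hold at least `min_genes` genes and span at most
#' `max_connections` tissues, and — when a focus set is given — when the
#' group contains at least one focus tissue. Node size is
#' `size_scale * sqrt(gene_count)`, the usual square-root area scaling.
#'
#' @param classification a `gene_classification` from [classify_profile()].
#' @param focus optional character vector of focus tissues; empty means no
#'   focus filtering.
#' @param min_genes minimum genes per group node (default 2).
#' @param max_connections maximum tissues per group node (default 5).
#' @param size_scale multiplier for node sizes (default 1).
#' @return a list of class `enrichment_graph` with data.frames `nodes`
#'   (`name`, `kind`, `gene_count`, `size`) and `edges` (`from`, `to`),
#'   both deterministically ordered (kind, then name).
#' @export
build_network <- function(classification, focus = character(),
                          min_genes = 2, max_connections = 5,
                          size_scale = 1) {
  stopifnot(inherits(classification, "gene_classification"))
  cls <- as.data.frame(classification)

  te <- cls[cls$category %in% c("highly_tissue_enriched",
                                "moderately_tissue_enriched"), ]
  te_counts <- table(te$enriched_tissue)
  te_names <- if (length(te_counts)) names(te_counts) else character()

  ge <- cls[cls$category == "group_enriched", ]
  ge_counts <- table(ge$enriched_group)
  if (length(ge_counts) > 0) {
    members <- strsplit(names(ge_counts), ";", fixed = TRUE)
    keep <- as.vector(ge_counts) >= min_genes &
      lengths(members) <= max_connections
    if (length(focus) > 0)
      keep <- keep & vapply(members, function(m) any(m %in% focus), logical(1))
    ge_counts <- ge_counts[keep]
    members <- members[keep]
  } else {
    members <- list()
  }
  ge_names <- if (length(ge_counts)) names(ge_counts) else character()

  set_nodes <- data.frame(
    name = c(paste0("TE:", te_names, recycle0 = TRUE),
             paste0("GE:", ge_names, recycle0 = TRUE)),
    kind = c(rep("tissue_enriched", length(te_counts)),
             rep("group_enriched", length(ge_counts))),
    gene_count = c(as.vector(te_counts), as.vector(ge_counts)),
    stringsAsFactors = FALSE)
  set_nodes$size <- size_scale * sqrt(set_nodes$gene_count)

  edge_from <- c(paste0("TE:", te_names, recycle0 = TRUE),
                 rep(paste0("GE:", ge_names, recycle0 = TRUE),
                     times = lengths(members)))
  edge_to <- c(te_names, unlist(members, use.names = FALSE))
  if (is.null(edge_to)) edge_to <- character()

  tissue_names <- sort(unique(edge_to))
  tissue_nodes <- data.frame(name = tissue_names,
                             kind = rep("tissue", length(tissue_names)),
                             gene_count = rep(NA_real_, length(tissue_names)),
                             size = rep(NA_real_, length(tissue_names)),
                             stringsAsFactors = FALSE)
  nodes <- rbind(set_nodes, tissue_nodes)
  nodes <- nodes[order(nodes$kind, nodes$name, method = "radix"), ,
                 drop = FALSE]
  rownames(nodes) <- NULL
  edges <- data.frame(from = edge_from, to = edge_to,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "enrichment_graph")
}

#' @export
print.enrichment_graph <- function(x, ...) {
  k <- table(factor(x$nodes$kind,
                    levels = c("tissue_enriched", "group_enriched", "tissue")))
  cat(sprintf(
    "enrichment_graph: %d tissue-enriched + %d group-enriched set nodes, %d tissues, %d edges\n",
    k[["tissue_enriched"]], k[["group_enriched"]], k[["tissue"]],
    nrow(x$edges)))
  invisible(x)
}

#' Export an enrichment network
#'
#' Writes Cytoscape-loadable files. SIF holds one edge per line
#' (`setnode member tissue`) plus isolated nodes on bare lines; GraphML
#' carries the `kind`, `gene_count` and `size` node attributes. Output is
#' byte-deterministic: nodes sorted by kind then name, edges by endpoint.
#'
#' @param g an `enrichment_graph`.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return invisibly, `path`.
#' @export
export_graph <- function(g, path, format = c("sif", "graphml")) {
  stopifnot(inherits(g, "enrichment_graph"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- "# enrichment network (SIF): setnode member tissue"
    if (nrow(g$edges) > 0)
      lines <- c(lines, paste(g$edges$from, "member", g$edges$to))
    linked <- unique(c(g$edges$from, g$edges$to))
    isolated <- setdiff(g$nodes$name, linked)
    lines <- c(lines, isolated)
    writeLines(lines, path)
  } else {
    num <- function(x) ifelse(is.na(x), "NA", format(x, digits = 15))
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="kind" for="node" attr.name="kind" attr.type="string"/>',
      '  <key id="gene_count" for="node" attr.name="gene_count" attr.type="double"/>',
      '  <key id="size" for="node" attr.name="size" attr.type="double"/>',
      '  <graph id="enrichment" edgedefault="undirected">')
    for (i in seq_len(nrow(g$nodes))) {
      nd <- g$nodes[i, ]
      lines <- c(lines,
        sprintf('    <node id="%s">', xml_escape(nd$name)),
        sprintf('      <data key="kind">%s</data>', nd$kind),
        sprintf('      <data key="gene_count">%s</data>', num(nd$gene_count)),
        sprintf('      <data key="size">%s</data>', num(nd$size)),
        '    </node>')
    }
    for (i in seq_len(nrow(g$edges))) {
      lines <- c(lines, sprintf('    <edge source="%s" target="%s"/>',
                                xml_escape(g$edges$from[i]),
                                xml_escape(g$edges$to[i])))
    }
    lines <- c(lines, "  </graph>", "</graphml>")
    writeLines(lines, path)
  }
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Read an enrichment network back from an exported file
#'
#' SIF input recovers nodes and edges (node kinds from the `TE:`/`GE:`
#' name prefixes; gene counts are not stored in SIF). GraphML input
#' recovers all node attributes. Re-exporting a parsed graph reproduces
#' the original file byte for byte.
#'
#' @param path file written by [export_graph()].
#' @param format `"sif"` or `"graphml"`.
#' @return an `enrichment_graph`.
#' @export
read_graph <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    parts <- strsplit(lines, " ", fixed = TRUE)
    is_edge <- lengths(parts) == 3
    edges <- data.frame(
      from = vapply(parts[is_edge], `[`, "", 1),
      to = vapply(parts[is_edge], `[`, "", 3),
      stringsAsFactors = FALSE)
    names_all <- unique(c(edges$from, edges$to,
                          vapply(parts[!is_edge], `[`, "", 1)))
    nodes <- data.frame(name = names_all,
                        kind = node_kind(names_all),
                        gene_count = NA_real_, size = NA_real_,
                        stringsAsFactors = FALSE)
  } else {
    doc <- xml2::read_xml(path)
    ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
    node_xml <- xml2::xml_find_all(doc, ".//g:node", ns)
    get_data <- function(n, key) {
      v <- xml2::xml_text(xml2::xml_find_first(
        n, sprintf("./g:data[@key='%s']", key), ns))
      v
    }
    nodes <- data.frame(
      name = xml2::xml_attr(node_xml, "id"),
      kind = vapply(node_xml, get_data, "", "kind"),
      gene_count = suppressWarnings(
        as.numeric(vapply(node_xml, get_data, "", "gene_count"))),
      size = suppressWarnings(
        as.numeric(vapply(node_xml, get_data, "", "size"))),
      stringsAsFactors = FALSE)
    edge_xml <- xml2::xml_find_all(doc, ".//g:edge", ns)
    edges <- data.frame(from = xml2::xml_attr(edge_xml, "source"),
                        to = xml2::xml_attr(edge_xml, "target"),
                        stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$kind, nodes$name, method = "radix"), ,
                 drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order(edges$from, edges$to, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "enrichment_graph")
}

node_kind <- function(name) {
  ifelse(startsWith(name, "TE:"), "tissue_enriched",
         ifelse(startsWith(name, "GE:"), "group_enriched", "tissue"))
}
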