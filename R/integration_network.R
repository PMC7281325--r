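#' Read a GMT gene-set collection
#'
#' @param path GMT file: per line, set name, description, then member
#'   symbols, tab-separated.
#' @return named list of character vectors; names are set names,
#'   descriptions kept in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("GMT lines must have name, description and >= 1 member")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' Read a protein-protein edge list
#'
#' @param path TSV with columns `symbol_a`, `symbol_b`, optional `score` and
#'   `source_db`.
#' @return data frame with those columns (`score` defaults to 1,
#'   `source_db` to `"file"`).
#' @export
read_edge_list <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("symbol_a", "symbol_b") %in% names(e)))
    stop("edge list needs columns symbol_a, symbol_b")
  if (is.null(e$score)) e$score <- 1
  if (is.null(e$source_db)) e$source_db <- "file"
  e[, c("symbol_a", "symbol_b", "score", "source_db")]
}

#' Build the integrated multi-omic network
#'
#' Merges phosphosite markers and treatment-independent genes into one node
#' set keyed by gene symbol. Phosphoprotein nodes carry the per-time-point
#' signed fold-change vector of the baseline (resistant vs parental)
#' contrast, with missing time points kept as explicit gaps; mRNA nodes
#' carry the signed expression fold change (mean of the two contrasts);
#' symbols found in both inputs become `both` nodes with both quantification
#' layers. Edges from the optional edge list are added when both endpoints
#' exist; edges referencing absent symbols are dropped with a warning.
#' Isolated nodes are kept.
#'
#' When several marker sites share a gene symbol the node keeps the fold
#' changes of the site with the largest |consensus fold change| and lists
#' every residue in the `sites` attribute.
#'
#' @param markers result of [select_markers()] / [discover_markers()] (needs
#'   `markers` element), or the marker data frame itself.
#' @param genes result of [select_resistance_genes()] (needs `table`
#'   element), or the gene data frame itself, or `NULL`.
#' @param edges optional edge data frame ([read_edge_list()]).
#' @param kinases optional character vector of kinase symbols to flag.
#' @return an undirected [igraph::graph] with vertex attributes `name`,
#'   `node_kind`, `sites`, `fc_<tp>` per phospho time point, `mrna_fc`,
#'   `regulation`, `is_kinase`; edge attributes `score`, `source_db`.
#' @export
build_network <- function(markers, genes = NULL, edges = NULL,
                          kinases = character()) {
  m <- if (is.data.frame(markers)) markers else markers$markers
  g <- if (is.null(genes)) NULL
       else if (is.data.frame(genes)) genes else genes$table

  fc_cols <- grep("^fc_A_", names(m), value = TRUE)
  tps <- sub("^fc_A_", "", fc_cols)

  pnodes <- NULL
  if (!is.null(m) && nrow(m) > 0) {
    m <- m[order(-abs(m$consensus_fc), m$site_key), , drop = FALSE]
    site_lab <- paste0(m$residue, m$position)
    agg_sites <- tapply(site_lab, m$gene_symbol,
                        function(x) paste(x, collapse = ";"))
    first <- !duplicated(m$gene_symbol)
    pnodes <- data.frame(symbol = m$gene_symbol[first],
                         regulation = m$consensus_direction[first],
                         stringsAsFactors = FALSE)
    for (i in seq_along(tps))
      pnodes[[paste0("fc_", tps[i])]] <- m[[fc_cols[i]]][first]
    pnodes$sites <- as.vector(agg_sites[pnodes$symbol])
  }

  gnodes <- NULL
  if (!is.null(g) && nrow(g) > 0) {
    gnodes <- data.frame(symbol = g$gene,
                         regulation = g$direction,
                         mrna_fc = (g$fc_baseline + g$fc_treated) / 2,
                         stringsAsFactors = FALSE)
  }

  symbols <- unique(c(pnodes$symbol, gnodes$symbol))
  if (length(symbols) == 0)
    return(igraph::make_empty_graph(0, directed = FALSE))
  kind <- ifelse(symbols %in% pnodes$symbol & symbols %in% gnodes$symbol,
                 "both",
                 ifelse(symbols %in% pnodes$symbol, "phosphoprotein",
                        "mRNA"))
  net <- igraph::make_empty_graph(0, directed = FALSE)
  net <- igraph::add_vertices(net, length(symbols), name = symbols,
                              node_kind = kind)
  pm <- if (is.null(pnodes)) rep(NA_integer_, length(symbols))
        else match(symbols, pnodes$symbol)
  gm <- if (is.null(gnodes)) rep(NA_integer_, length(symbols))
        else match(symbols, gnodes$symbol)
  pcol <- function(col, default) {
    if (is.null(pnodes)) rep(default, length(symbols))
    else pnodes[[col]][pm]
  }
  for (tp in tps)
    net <- igraph::set_vertex_attr(net, paste0("fc_", tp),
                                   value = pcol(paste0("fc_", tp), NA_real_))
  sites <- pcol("sites", NA_character_)
  net <- igraph::set_vertex_attr(net, "sites",
                                 value = ifelse(is.na(sites), "", sites))
  mrna <- if (is.null(gnodes)) rep(NA_real_, length(symbols))
          else gnodes$mrna_fc[gm]
  net <- igraph::set_vertex_attr(net, "mrna_fc", value = mrna)
  greg <- if (is.null(gnodes)) rep(NA_character_, length(symbols))
          else gnodes$regulation[gm]
  preg <- pcol("regulation", NA_character_)
  net <- igraph::set_vertex_attr(net, "regulation",
                                 value = ifelse(!is.na(preg), preg, greg))
  net <- igraph::set_vertex_attr(net, "is_kinase",
                                 value = symbols %in% kinases)

  if (!is.null(edges) && nrow(edges) > 0) {
    known <- edges$symbol_a %in% symbols & edges$symbol_b %in% symbols
    if (any(!known))
      warning(sum(!known), " edge(s) referencing absent symbols dropped")
    e <- edges[known, , drop = FALSE]
    if (nrow(e) > 0) {
      net <- igraph::add_edges(net,
                               rbind(match(e$symbol_a, symbols),
                                     match(e$symbol_b, symbols)),
                               score = e$score, source_db = e$source_db)
    }
  }
  net
}

#' Hypergeometric gene-set enrichment
#'
#' For each term, tests over-representation of the selected symbols with the
#' upper-tail hypergeometric probability `P(X >= k)` where `X ~
#' Hypergeometric(N, K, n)`: `N` universe size, `K` term members in the
#' universe, `n` selected, `k` selected term members. Terms with no member
#' in the universe are skipped; q-values are Benjamini-Hochberg across all
#' tested terms.
#'
#' @param selected character vector, a subset of `universe`.
#' @param universe character vector of all measured symbols.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @return data frame with `term`, `N`, `K`, `n`, `k`, `p`, `q`, `members`
#'   (semicolon-joined selected members), ordered by p then term.
#' @export
hypergeometric_enrichment <- function(selected, universe, gene_sets) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (!all(selected %in% universe))
    stop("selected symbols must be a subset of the universe")
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(gene_sets[[term]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    hit <- intersect(members, selected)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, N = N, K = K, n = n, k = k, p = p,
               members = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(term = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p = numeric(),
                      q = numeric(), members = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term),
             c("term", "N", "K", "n", "k", "p", "q", "members")]
  rownames(out) <- NULL
  out
}

#' Export / import the integrated network
#'
#' GraphML and Cytoscape-JSON round-trip all node and edge attributes with
#' deterministic element ordering; `edge_tsv` writes the edge list with
#' endpoint symbols (lossy: node attributes are not included). Missing
#' per-time-point quantifications serialize as explicit nulls (Cytoscape
#' JSON) or absent data elements (GraphML) and are restored as `NA`.
#'
#' @param network an igraph object from [build_network()].
#' @param path output file.
#' @param format one of `"graphml"`, `"cyjs"`, `"edge_tsv"`.
#' @return invisibly, `path`.
#' @export
export_graph <- function(network, path,
                         format = c("graphml", "cyjs", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else if (format == "cyjs") {
    vat <- igraph::vertex_attr(network)
    nodes <- lapply(seq_len(igraph::vcount(network)), function(i) {
      data <- lapply(vat, `[[`, i)
      data$id <- data$name
      list(data = data)
    })
    eat <- igraph::edge_attr(network)
    ends <- igraph::as_edgelist(network)
    edges <- lapply(seq_len(igraph::ecount(network)), function(i) {
      data <- lapply(eat, `[[`, i)
      data$source <- ends[i, 1]
      data$target <- ends[i, 2]
      list(data = data)
    })
    jsonlite::write_json(
      list(format_version = "1.0",
           elements = list(nodes = nodes, edges = edges)),
      path, auto_unbox = TRUE, null = "null", na = "null", digits = NA,
      pretty = TRUE)
  } else {
    ends <- igraph::as_edgelist(network)
    e <- data.frame(symbol_a = ends[, 1], symbol_b = ends[, 2],
                    stringsAsFactors = FALSE)
    for (a in names(igraph::edge_attr(network)))
      e[[a]] <- igraph::edge_attr(network, a)
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "cyjs")) {
  format <- match.arg(format)
  if (format == "graphml") {
    net <- igraph::read_graph(path, format = "graphml")
    net <- igraph::delete_vertex_attr(net, "id")
    for (a in names(igraph::vertex_attr(net))) {
      v <- igraph::vertex_attr(net, a)
      if (is.numeric(v) && any(is.nan(v)))
        net <- igraph::set_vertex_attr(net, a,
                                       value = ifelse(is.nan(v), NA, v))
    }
    return(net)
  }
  doc <- jsonlite::read_json(path)
  nodes <- doc$elements$nodes
  edges <- doc$elements$edges
  getv <- function(items, field)
    lapply(items, function(x) x$data[[field]])
  simplify_attr <- function(v)
    unlist(lapply(v, function(x) if (is.null(x)) NA else x))
  net <- igraph::make_empty_graph(0, directed = FALSE)
  nms <- simplify_attr(getv(nodes, "name"))
  net <- igraph::add_vertices(net, length(nodes), name = nms)
  if (length(nodes) > 0) {
    fields <- setdiff(unique(unlist(lapply(nodes,
                                           function(x) names(x$data)))),
                      c("id", "name"))
    for (f in fields)
      net <- igraph::set_vertex_attr(net, f,
                                     value = simplify_attr(getv(nodes, f)))
  }
  if (length(edges) > 0) {
    src <- simplify_attr(getv(edges, "source"))
    dst <- simplify_attr(getv(edges, "target"))
    net <- igraph::add_edges(net, rbind(match(src, nms), match(dst, nms)))
    fields <- setdiff(unique(unlist(lapply(edges,
                                           function(x) names(x$data)))),
                      c("source", "target"))
    for (f in fields)
      net <- igraph::set_edge_attr(net, f,
                                   value = simplify_attr(getv(edges, f)))
  }
  net
}
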