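# Cross-block feature association scores and network export.

#' Cross-block similarity matrix
#'
#' `M[i, j] = sum_{h <= ncomp} cor(x_i, t_h^a) * cor(y_j, t_h^b)`, where
#' `t^a`, `t^b` are the component scores of each variable's own block (for a
#' two-block PLS model: the X-scores and Y-scores). Bounded by 1 in absolute
#' value when the within-block scores are orthogonal.
#'
#' @param model A fitted two-block or multiblock `latent_model`.
#' @param block_a,block_b Block names.
#' @param ncomp Number of components summed (default: all fitted).
#' @return Numeric matrix (features of `block_a` x features of `block_b`)
#'   with a `blocks` attribute.
#' @export
similarity_matrix <- function(model, block_a, block_b, ncomp = NULL) {
  H <- ncomp %||% model$ncomp
  if (H > model$ncomp) stop("ncomp exceeds the fitted model", call. = FALSE)
  for (nm in c(block_a, block_b)) {
    if (is.null(model$blocks[[nm]])) {
      stop("unknown block '", nm, "'", call. = FALSE)
    }
  }
  ba <- model$blocks[[block_a]]; bb <- model$blocks[[block_b]]
  Ca <- stats::cor(ba$data, ba$scores[, seq_len(H), drop = FALSE])
  Cb <- stats::cor(bb$data, bb$scores[, seq_len(H), drop = FALSE])
  M <- tcrossprod(Ca, Cb)
  attr(M, "blocks") <- c(block_a, block_b)
  M
}

node_id <- function(block, feature) paste(block, feature, sep = ":")

#' Threshold similarity scores into a feature association network
#'
#' Keeps every cross-block edge whose absolute weight is strictly greater
#' than the cutoff, then drops nodes left without edges. Raising the cutoff
#' never adds edges.
#'
#' @param sim A similarity matrix from [similarity_matrix()] (with its
#'   `blocks` attribute) or a list of such matrices.
#' @param cutoff Absolute-correlation cutoff in `[0, 1]`.
#' @return A `similarity_network`: `nodes` (id, feature, block), `edges`
#'   (from, to, weight) and the cutoff.
#' @export
build_network <- function(sim, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  mats <- if (is.matrix(sim)) list(sim) else sim
  edges <- list()
  for (M in mats) {
    blk <- attr(M, "blocks") %||% c("X", "Y")
    hits <- which(abs(M) > cutoff, arr.ind = TRUE)
    if (nrow(hits)) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = node_id(blk[1L], rownames(M)[hits[, 1L]]),
        to = node_id(blk[2L], colnames(M)[hits[, 2L]]),
        from_feature = rownames(M)[hits[, 1L]],
        to_feature = colnames(M)[hits[, 2L]],
        from_block = blk[1L], to_block = blk[2L],
        weight = M[hits],
        stringsAsFactors = FALSE
      )
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(),
               from_feature = character(), to_feature = character(),
               from_block = character(), to_block = character(),
               weight = numeric(), stringsAsFactors = FALSE)
  nodes <- unique(rbind(
    data.frame(id = edges$from, feature = edges$from_feature,
               block = edges$from_block, stringsAsFactors = FALSE),
    data.frame(id = edges$to, feature = edges$to_feature,
               block = edges$to_block, stringsAsFactors = FALSE)
  ))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(
    list(nodes = nodes,
         edges = edges[, c("from", "to", "weight")],
         cutoff = cutoff),
    class = "similarity_network"
  )
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes, %d edges (|weight| > %g)\n",
              nrow(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Cross-block edges of a multiblock model (circos data layer)
#'
#' Union of [build_network()] over all data-block pairs of a multiblock
#' model. Per-feature class-mean expression profiles (on the standardized
#' scale) are attached for the outer lines of a circos rendering.
#'
#' @param model A `latent_model` from [fit_diablo()].
#' @param cutoff Absolute-correlation cutoff (default 0.8).
#' @param ncomp Components summed in the similarity scores (default: all).
#' @return A `similarity_network` with an extra `profiles` data frame
#'   (id, feature, block, class, mean).
#' @export
circos_edges <- function(model, cutoff = 0.8, ncomp = NULL) {
  if (model$algorithm != "diablo") {
    stop("circos_edges() needs a multiblock model", call. = FALSE)
  }
  bn <- model$block_names
  if (length(bn) < 2L) stop("need at least two blocks", call. = FALSE)
  combs <- utils::combn(bn, 2L)
  sims <- lapply(seq_len(ncol(combs)), function(i)
    similarity_matrix(model, combs[1L, i], combs[2L, i], ncomp = ncomp))
  net <- build_network(sims, cutoff)
  labels <- model$labels
  cls <- sort(unique(labels))
  prof <- list()
  for (i in seq_len(nrow(net$nodes))) {
    nd <- net$nodes[i, ]
    x <- model$blocks[[nd$block]]$data[, nd$feature]
    prof[[i]] <- data.frame(id = nd$id, feature = nd$feature,
                            block = nd$block, class = cls,
                            mean = vapply(cls, function(cl)
                              mean(x[labels == cl]), 1),
                            stringsAsFactors = FALSE)
  }
  net$profiles <- if (length(prof)) do.call(rbind, prof) else
    data.frame(id = character(), feature = character(), block = character(),
               class = character(), mean = numeric())
  rownames(net$profiles) <- NULL
  net
}

#' Export a feature association network
#'
#' GraphML (via igraph) or JSON with node attributes (feature, block, color)
#' and edge weights; round-trips losslessly through [read_network()].
#'
#' @param net A `similarity_network`.
#' @param path Output file.
#' @param format `"graphml"` or `"json"`.
#' @param block_colors Optional named hex colors per block (a default
#'   palette is used otherwise).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "json"),
                           block_colors = NULL) {
  format <- match.arg(format)
  nodes <- net$nodes
  blocks <- sort(unique(nodes$block))
  if (is.null(block_colors)) {
    block_colors <- stats::setNames(default_palette(length(blocks)), blocks)
  }
  nodes$color <- unname(block_colors[nodes$block])
  if (nrow(nodes) == 0L) nodes$color <- character(0)
  if (format == "json") {
    jsonlite::write_json(
      list(nodes = nodes, edges = net$edges, cutoff = net$cutoff),
      path, auto_unbox = TRUE, digits = NA, null = "null"
    )
  } else {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"json"`.
#' @return A `similarity_network` (cutoff is only recoverable from JSON).
#' @export
read_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as.data.frame(x$nodes, stringsAsFactors = FALSE)
    edges <- as.data.frame(x$edges, stringsAsFactors = FALSE)
    if (nrow(nodes)) nodes$color <- NULL
    structure(list(nodes = nodes, edges = edges, cutoff = x$cutoff),
              class = "similarity_network")
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    vattr <- igraph::vertex_attr(g)
    nodes <- data.frame(id = vattr$name,
                        feature = vattr$feature,
                        block = vattr$block, stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(from = el[, 1L], to = el[, 2L],
                        weight = igraph::edge_attr(g, "weight"),
                        stringsAsFactors = FALSE)
    structure(list(nodes = nodes, edges = edges, cutoff = NA_real_),
              class = "similarity_network")
  }
}
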