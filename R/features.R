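#' Bundle the confidence-head input features
#'
#' Container for the four per-residue / per-residue-pair feature tensors
#' consumed by the confidence head, plus the ensemble RMSF column:
#' the single representation (L x 384), the pair representation
#' (L x L x 128), the layer-averaged language-model embedding (L x 33),
#' the layer/head-averaged language-model attention map (L x L x 33) and
#' RMSF (L x 1). Ablation flags switch feature groups off without changing
#' the container.
#'
#' @param single L x 384 numeric matrix.
#' @param pair L x L x 128 numeric array.
#' @param esm_embed L x 33 numeric matrix.
#' @param esm_attn L x L x 33 numeric array.
#' @param rmsf length-L numeric vector (Angstrom).
#' @param ablation list of logical flags `use_rmsf`, `use_esm`, `use_edges`,
#'   `use_extra` (all default TRUE). `use_extra = FALSE` is the
#'   single-representation-only variant: node features reduce to `single`
#'   and edge features to `pair`.
#' @return object of class `feature_bundle`.
#' @export
feature_bundle <- function(single, pair, esm_embed, esm_attn, rmsf,
                           ablation = list()) {
  L <- nrow(single)
  stopifnot(ncol(single) == 384,
            identical(dim(pair), c(L, L, 128L)) || identical(dim(pair), as.integer(c(L, L, 128))),
            nrow(esm_embed) == L, ncol(esm_embed) == 33,
            identical(dim(esm_attn)[1:2], dim(pair)[1:2]), dim(esm_attn)[3] == 33,
            length(rmsf) == L)
  ab <- utils::modifyList(list(use_rmsf = TRUE, use_esm = TRUE,
                               use_edges = TRUE, use_extra = TRUE), ablation)
  tensors <- list(single = single, pair = pair, esm_embed = esm_embed,
                  esm_attn = esm_attn, rmsf = as.numeric(rmsf))
  if (!all(vapply(tensors, function(x) all(is.finite(x)), logical(1)))) {
    stop("feature tensors must be finite")
  }
  structure(c(tensors, list(L = L, ablation = ab)), class = "feature_bundle")
}

#' @export
print.feature_bundle <- function(x, ...) {
  on <- names(Filter(isTRUE, x$ablation))
  cat(sprintf("<feature_bundle> L = %d; flags on: %s\n", x$L,
              paste(on, collapse = ", ")))
  invisible(x)
}

#' Write / read a feature bundle
#'
#' Bundles are stored as an RDS file holding the named arrays
#' `single`, `pair`, `esm_embed`, `esm_attn`, `rmsf` plus `L` and the
#' ablation flags — a documented layout into which externally computed
#' tensors (structure-prediction trunk, language model) can be exported.
#'
#' @param bundle a `feature_bundle`.
#' @param path file path.
#' @return `read_feature_bundle` returns a `feature_bundle`.
#' @export
write_feature_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "feature_bundle"))
  saveRDS(unclass(bundle), path)
  invisible(path)
}

#' @rdname write_feature_bundle
#' @export
read_feature_bundle <- function(path) {
  x <- readRDS(path)
  feature_bundle(x$single, x$pair, x$esm_embed, x$esm_attn, x$rmsf,
                 ablation = x$ablation)
}

#' Build the CA contact edge list
#'
#' Directed edges i -> j for every ordered pair of residues whose CA atoms
#' lie within the cutoff (inclusive) of each other; no self loops. The edge
#' set is symmetric as a set of unordered pairs.
#'
#' @param coords L x 3 matrix of CA coordinates in Angstrom.
#' @param cutoff contact cutoff in Angstrom (default 16).
#' @return integer matrix (E x 2) with columns `i`, `j`.
#' @export
build_edges <- function(coords, cutoff = 16) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 residues")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  D <- .pairdist(coords)
  keep <- which(D <= cutoff & upper.tri(D), arr.ind = TRUE)
  e <- rbind(keep, keep[, 2:1, drop = FALSE])
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  colnames(e) <- c("i", "j")
  rownames(e) <- NULL
  storage.mode(e) <- "integer"
  e
}

#' Assemble the protein graph for the confidence head
#'
#' Concatenates raw node features (single representation, plus language
#' model embedding and RMSF when enabled) and raw edge features (pair
#' representation slice, plus attention slice when enabled) onto the CA
#' contact graph. This is a pure rearrangement of bundle entries; the
#' learned transition layers are applied inside the head. Edge i -> j
#' carries `pair[i, j, ]` (orientation preserved; both directed edges
#' exist). With `use_edges = FALSE` the graph connectivity is retained but
#' the edge feature block is empty — messages then see only the
#' inter-residue distance term. With `use_extra = FALSE` node features are
#' the single representation alone and edge features the pair
#' representation alone.
#'
#' @param bundle a [feature_bundle()].
#' @param coords L x 3 CA coordinates of the model being assessed.
#' @param residue_indices length-L integer vector of residue indices.
#' @param cutoff CA contact cutoff in Angstrom.
#' @return object of class `protein_graph` with fields `coords`,
#'   `node_input`, `edges`, `edge_input`, `residue_indices`, `ablation`.
#' @export
assemble_graph <- function(bundle, coords, residue_indices,
                           cutoff = 16) {
  stopifnot(inherits(bundle, "feature_bundle"))
  coords <- as.matrix(coords)
  L <- bundle$L
  if (nrow(coords) != L || length(residue_indices) != L) {
    stop("bundle, coords and residue_indices disagree on L")
  }
  ab <- bundle$ablation
  if (!ab$use_extra) {
    node <- bundle$single
  } else {
    node <- bundle$single
    if (ab$use_esm) node <- cbind(node, bundle$esm_embed)
    if (ab$use_rmsf) node <- cbind(node, bundle$rmsf)
  }
  edges <- build_edges(coords, cutoff)
  E <- nrow(edges)
  if (!ab$use_edges) {
    edge_input <- matrix(numeric(0), nrow = E, ncol = 0)
  } else {
    idx <- cbind(edges[, 1], edges[, 2])
    pair_slice <- apply(bundle$pair, 3, function(m) m[idx])
    if (E == 1) pair_slice <- matrix(pair_slice, nrow = 1)
    if (ab$use_extra && ab$use_esm) {
      attn_slice <- apply(bundle$esm_attn, 3, function(m) m[idx])
      if (E == 1) attn_slice <- matrix(attn_slice, nrow = 1)
      edge_input <- cbind(pair_slice, attn_slice)
    } else {
      edge_input <- pair_slice
    }
  }
  structure(list(coords = coords, node_input = node, edges = edges,
                 edge_input = edge_input,
                 residue_indices = as.integer(residue_indices),
                 ablation = ab),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat(sprintf(
    "<protein_graph> L = %d, %d directed edges, node dim %d, edge dim %d\n",
    nrow(x$coords), nrow(x$edges), ncol(x$node_input), ncol(x$edge_input)))
  invisible(x)
}
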