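#' LDDT scoring configuration
#'
#' @param inclusion_radius inclusion radius in Angstrom: only atom pairs
#'   within this distance *in the reference structure* are scored.
#' @param thresholds strictly increasing distance-difference tolerances in
#'   Angstrom; a pair contributes one point per tolerance it satisfies.
#' @param mode `"calpha"` scores CA atoms only; `"all_atom"` scores every
#'   heavy atom of the residue of interest and averages per residue (the
#'   more stringent all-atom variant).
#' @param min_sequence_separation residue pairs with |i - j| less than or
#'   equal to this are excluded; the default 0 excludes only intra-residue
#'   pairs.
#' @return an object of class `lddt_config`.
#' @export
lddt_config <- function(inclusion_radius = 15, thresholds = c(0.5, 1, 2, 4),
                        mode = c("calpha", "all_atom"),
                        min_sequence_separation = 0L) {
  mode <- match.arg(mode)
  stopifnot(inclusion_radius > 0, all(thresholds > 0),
            all(diff(thresholds) > 0), min_sequence_separation >= 0)
  structure(list(inclusion_radius = inclusion_radius,
                 thresholds = as.numeric(thresholds), mode = mode,
                 min_sequence_separation = as.integer(min_sequence_separation)),
            class = "lddt_config")
}

new_lddt_profile <- function(per_residue) {
  defined <- per_residue[!is.na(per_residue)]
  structure(list(per_residue = per_residue,
                 model_level = if (length(defined)) mean(defined) else NA_real_),
            class = "lddt_profile")
}

#' @export
print.lddt_profile <- function(x, ...) {
  d <- x$per_residue[!is.na(x$per_residue)]
  cat(sprintf("<lddt_profile> %d scored residues, model-level %.2f\n",
              length(d), x$model_level))
  invisible(x)
}

# atom table restricted to the scoring mode, keyed by "resno|elety"
.score_atoms <- function(model, mode) {
  at <- model$atoms
  if (mode == "calpha") at <- at[at$elety == "CA", , drop = FALSE]
  at$key <- paste(at$resno, at$elety, sep = "|")
  at
}

#' Reference-structure inclusion pairs of one residue
#'
#' Enumerates the atom pairs that enter the LDDT score of a residue: in
#' CA mode, pairs between the residue's CA and every other residue's CA
#' within the inclusion radius; in all-atom mode, pairs between each heavy
#' atom of the residue and every heavy atom of other residues within the
#' radius. Distances are measured in the reference structure only.
#'
#' @param reference a `structure_model` (the ground-truth structure).
#' @param residue_index residue of interest (1-based sequence position).
#' @param config an [lddt_config()].
#' @return data.frame with columns `resno_i`, `atom_i`, `resno_j`, `atom_j`,
#'   `d_ref`.
#' @export
inclusion_pairs <- function(reference, residue_index, config = lddt_config()) {
  at <- .score_atoms(reference, config$mode)
  if (!(residue_index %in% at$resno)) {
    stop("residue ", residue_index, " not present in reference")
  }
  a <- at[at$resno == residue_index, , drop = FALSE]
  b <- at[abs(at$resno - residue_index) > config$min_sequence_separation, ,
          drop = FALSE]
  if (nrow(b) == 0) {
    return(data.frame(resno_i = integer(), atom_i = character(),
                      resno_j = integer(), atom_j = character(),
                      d_ref = numeric()))
  }
  out <- vector("list", nrow(a))
  for (k in seq_len(nrow(a))) {
    d <- sqrt((b$x - a$x[k])^2 + (b$y - a$y[k])^2 + (b$z - a$z[k])^2)
    keep <- d <= config$inclusion_radius
    nk <- sum(keep)
    out[[k]] <- data.frame(resno_i = rep(residue_index, nk),
                           atom_i = rep(a$elety[k], nk),
                           resno_j = b$resno[keep], atom_j = b$elety[keep],
                           d_ref = d[keep], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Local Distance Difference Test (LDDT)
#'
#' Superposition-free per-residue model quality: for each residue of the
#' reference, every (atom pair, tolerance threshold) combination within the
#' reference-structure inclusion radius is checked for preservation of the
#' inter-atomic distance in the model; the residue score is 100 times the
#' fraction preserved. In all-atom mode a per-atom score is computed from
#' that atom's pairs and the residue score is the mean over the residue's
#' heavy atoms present in both structures. Scoring is restricted to
#' residues (and atoms) present in both structures; residues whose pair set
#' is empty are undefined (NA) and excluded from the model-level mean.
#'
#' @param reference ground-truth `structure_model`.
#' @param model predicted `structure_model`, sharing residue indexing.
#' @param config an [lddt_config()].
#' @param method `"fast"` (vectorized distance matrices with radius
#'   prefilter) or `"reference"` (plain nested-loop scan; the independent
#'   oracle used to validate the fast path). Both return identical scores.
#' @return an `lddt_profile`: `per_residue` (named by residue index, NA
#'   where undefined) and `model_level` (mean of defined scores).
#' @export
compute_lddt <- function(reference, model, config = lddt_config(),
                         method = c("fast", "reference")) {
  method <- match.arg(method)
  ra <- .score_atoms(reference, config$mode)
  ma <- .score_atoms(model, config$mode)
  shared <- intersect(ra$key, ma$key)
  if (length(shared) == 0) stop("no shared residues/atoms between structures")
  ra <- ra[match(shared, ra$key), , drop = FALSE]
  ma <- ma[match(shared, ma$key), , drop = FALSE]
  res_all <- sort(unique(reference$atoms$resno))
  scored_res <- sort(intersect(unique(ra$resno), unique(model$atoms$resno)))
  if (method == "fast") {
    per_res <- .lddt_fast(ra, ma, config)
  } else {
    per_res <- .lddt_reference(ra, ma, config)
  }
  out <- setNames(rep(NA_real_, length(res_all)), res_all)
  out[names(per_res)] <- per_res
  new_lddt_profile(out)
}

# Vectorized path: full pairwise distance matrices on the shared atoms,
# inclusion mask from the reference, threshold counting by matrix sweeps.
.lddt_fast <- function(ra, ma, config) {
  n <- nrow(ra)
  P <- as.matrix(ra[, c("x", "y", "z")])
  Q <- as.matrix(ma[, c("x", "y", "z")])
  Dref <- .pairdist(P)
  Dmod <- .pairdist(Q)
  sep <- abs(outer(ra$resno, ra$resno, "-"))
  mask <- Dref <= config$inclusion_radius & sep > config$min_sequence_separation
  diag(mask) <- FALSE
  npairs <- rowSums(mask)
  dd <- abs(Dref - Dmod)
  hits <- numeric(n)
  for (t in config$thresholds) hits <- hits + rowSums((dd <= t) & mask)
  atom_score <- ifelse(npairs > 0,
                       100 * hits / (npairs * length(config$thresholds)),
                       NA_real_)
  ok <- !is.na(atom_score)
  res_score <- tapply(atom_score[ok], ra$resno[ok], mean)
  setNames(as.numeric(res_score), names(res_score))
}

.pairdist <- function(X) {
  g <- tcrossprod(X)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Brute-force oracle path: an O(n^2) scan, one atom at a time, with no
# distance-matrix algebra or neighbor prefilter shared with the fast path.
.lddt_reference <- function(ra, ma, config) {
  n <- nrow(ra)
  atom_score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dref <- sqrt((ra$x - ra$x[i])^2 + (ra$y - ra$y[i])^2 + (ra$z - ra$z[i])^2)
    keep <- seq_len(n) != i &
      abs(ra$resno - ra$resno[i]) > config$min_sequence_separation &
      dref <= config$inclusion_radius
    if (!any(keep)) next
    dmod <- sqrt((ma$x[keep] - ma$x[i])^2 + (ma$y[keep] - ma$y[i])^2 +
                   (ma$z[keep] - ma$z[i])^2)
    dd <- abs(dref[keep] - dmod)
    hits <- 0L
    for (t in config$thresholds) hits <- hits + sum(dd <= t)
    atom_score[i] <- 100 * hits / (sum(keep) * length(config$thresholds))
  }
  ok <- !is.na(atom_score)
  res_score <- tapply(atom_score[ok], ra$resno[ok], mean)
  setNames(as.numeric(res_score), names(res_score))
}

#' Per-residue LDDT error
#'
#' Absolute difference between a predicted and a true per-residue score.
#'
#' @param pred,true `lddt_profile` objects sharing residue indexing.
#' @param residue_index residue of interest.
#' @return |pred_i - true_i|.
#' @export
residue_error <- function(pred, true, residue_index) {
  p <- pred$per_residue[as.character(residue_index)]
  t <- true$per_residue[as.character(residue_index)]
  if (anyNA(p) || anyNA(t)) stop("residue ", residue_index,
                                 " undefined in one of the profiles")
  unname(abs(p - t))
}

#' Model-level LDDT error
#'
#' Mean absolute per-residue error over residues defined in both profiles.
#'
#' @param pred,true `lddt_profile` objects.
#' @return mean absolute error (scalar).
#' @export
model_error <- function(pred, true) {
  common <- intersect(names(pred$per_residue)[!is.na(pred$per_residue)],
                      names(true$per_residue)[!is.na(true$per_residue)])
  if (!length(common)) stop("no residue defined in both profiles")
  mean(abs(pred$per_residue[common] - true$per_residue[common]))
}

#' LDDT confidence category
#'
#' The four bands used for per-residue confidence annotation: very high
#' (>90), confident (70-90), low (50-70) and very low (<50). Boundaries are
#' assigned downward: 90 falls in "70-90", 70 in "50-70", 50 in "<50".
#'
#' @param score numeric vector of scores in \[0, 100\].
#' @return character vector with values among `">90"`, `"70-90"`,
#'   `"50-70"`, `"<50"`.
#' @export
lddt_category <- function(score) {
  if (any(score < 0 | score > 100, na.rm = TRUE)) {
    stop("scores must lie in [0, 100]")
  }
  out <- ifelse(score > 90, ">90",
                ifelse(score > 70, "70-90",
                       ifelse(score > 50, "50-70", "<50")))
  out[is.na(score)] <- NA_character_
  out
}

#' @rdname lddt_category
#' @export
lddt_categories <- function() c(">90", "70-90", "50-70", "<50")
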