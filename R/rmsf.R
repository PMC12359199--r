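#' Least-squares superposition of one model onto another
#'
#' Computes the optimal (Kabsch) rotation and translation of the mobile
#' model's CA atoms onto the target's over their shared residues, applies
#' it to every atom of the mobile model, and reports the CA RMSD after
#' superposition.
#'
#' @param mobile,target `structure_model` objects sharing residue indexing,
#'   with at least 3 shared CA atoms.
#' @return list with `model` (transformed copy of `mobile`), `rmsd`
#'   (CA RMSD in Angstrom), `rotation` (3x3), `translation` (length 3).
#' @export
superpose <- function(mobile, target) {
  cm <- ca_coords(mobile)
  ct <- ca_coords(target)
  common <- intersect(rownames(cm), rownames(ct))
  if (length(common) < 3) stop("need at least 3 shared CA atoms to superpose")
  A <- cm[common, , drop = FALSE]
  B <- ct[common, , drop = FALSE]
  fit <- .kabsch(A, B)
  at <- mobile$atoms
  X <- as.matrix(at[, c("x", "y", "z")])
  Xt <- sweep(X, 2, fit$center_a) %*% fit$R
  Xt <- sweep(Xt, 2, fit$center_b, "+")
  at[, c("x", "y", "z")] <- Xt
  moved <- structure_model(at, chain_id = mobile$chain_id,
                           sequence = mobile$sequence)
  At <- sweep(sweep(A, 2, fit$center_a) %*% fit$R, 2, fit$center_b, "+")
  rmsd <- sqrt(mean(rowSums((At - B)^2)))
  list(model = moved, rmsd = rmsd, rotation = fit$R,
       translation = as.numeric(fit$center_b - fit$center_a %*% fit$R))
}

# Kabsch via SVD; proper rotation enforced. Degenerate (collinear) sets give
# a rank-deficient covariance and are flagged.
.kabsch <- function(A, B) {
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)
  s <- svd(H)
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-12)) {
    warning("near-degenerate (collinear) point set; rotation ill-determined")
  }
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(R = R, center_a = ca, center_b = cb)
}

#' Construct an ensemble of structure models
#'
#' @param members list of `structure_model` objects sharing residue
#'   indexing (typically the 5 dropout replicates of a predictor).
#' @param reference_member index of the member used as superposition anchor.
#' @return object of class `ensemble`.
#' @export
ensemble <- function(members, reference_member = 1L) {
  stopifnot(length(members) >= 2,
            all(vapply(members, inherits, logical(1), "structure_model")))
  common <- Reduce(intersect, lapply(members, function(m) rownames(ca_coords(m))))
  if (length(common) < 3) stop("ensemble members share fewer than 3 CA atoms")
  structure(list(members = members,
                 reference_member = as.integer(reference_member)),
            class = "ensemble")
}

#' Per-residue root mean square fluctuation of an ensemble
#'
#' Superposes every member onto the anchor member (CA atoms, shared
#' residues, single pass), then for each residue present in all members
#' computes the RMS deviation of its CA position about the member-mean
#' position. Large fluctuation marks residues the predictor places
#' inconsistently — a proxy for local modeling uncertainty.
#'
#' @param ens an [ensemble()].
#' @return object of class `rmsf_profile`: named numeric vector
#'   `per_residue` of fluctuations in Angstrom (NA for residues absent from
#'   any member).
#' @export
compute_rmsf <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  anchor <- ens$members[[ens$reference_member]]
  fitted <- lapply(seq_along(ens$members), function(i) {
    if (i == ens$reference_member) return(ens$members[[i]])
    superpose(ens$members[[i]], anchor)$model
  })
  mats <- lapply(fitted, ca_coords)
  common <- Reduce(intersect, lapply(mats, rownames))
  if (!length(common)) stop("no residue present in every ensemble member")
  arr <- vapply(mats, function(m) m[common, , drop = FALSE],
                matrix(0, length(common), 3))
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- vapply(seq_along(mats), function(k) {
    rowSums((arr[, , k] - mean_pos)^2)
  }, numeric(length(common)))
  vals <- sqrt(rowMeans(dev2))
  all_res <- rownames(mats[[ens$reference_member]])
  out <- setNames(rep(NA_real_, length(all_res)), all_res)
  out[common] <- vals
  structure(list(per_residue = out), class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  d <- x$per_residue[!is.na(x$per_residue)]
  cat(sprintf("<rmsf_profile> %d residues, mean %.3f A, max %.3f A\n",
              length(d), mean(d), max(d)))
  invisible(x)
}
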