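# Synthetic structures, decoys, ensembles and feature tensors with known
# ground truth, so scoring, training and evaluation are testable end to end
# without any external structure or feature download.

.seed_stream <- function(master, counter) {
  # deterministic per-fixture seeds derived from one master seed
  as.integer((as.numeric(master) * 48271 + counter * 100003) %% 2147483629) + 1L
}

.maybe_seed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
}

#' Specification for one synthetic protein fixture
#'
#' @param length residue count L.
#' @param error_segments data.frame with columns `start`, `end`, `sigma`:
#'   residues in \[start, end\] receive i.i.d. Gaussian coordinate noise of
#'   that sigma (Angstrom) in the decoy; overlaps take the largest sigma.
#' @param base_sigma noise applied outside error segments (Angstrom).
#' @param ensemble_size number of ensemble replicates (default 5, matching
#'   the usual number of dropout replicates).
#' @param ensemble_jitter_scale multiplier linking injected per-residue
#'   error to ensemble fluctuation: jitter sd of residue i is
#'   `ensemble_jitter_scale * (100 - true_lddt_i) / 100` Angstrom.
#' @param feature_snr signal-to-noise ratio of the quality signal embedded
#'   in the feature tensors (0 = pure noise).
#' @param sidechain_noise_mult multiplier on the decoy noise of side-chain
#'   atoms (every heavy atom other than N, CA, C, O). Structure predictors
#'   place side chains less accurately than the backbone, which is what
#'   makes all-atom LDDT the more stringent score; 1 gives uniform noise.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(length, error_segments = NULL, base_sigma = 0.1,
                           ensemble_size = 5L, ensemble_jitter_scale = 1,
                           feature_snr = 10, sidechain_noise_mult = 1.5,
                           seed = NULL) {
  if (is.null(error_segments)) {
    error_segments <- data.frame(start = integer(), end = integer(),
                                 sigma = numeric())
  }
  stopifnot(length >= 2, all(error_segments$start >= 1),
            all(error_segments$end <= length),
            all(error_segments$start <= error_segments$end),
            all(error_segments$sigma >= 0), base_sigma >= 0,
            ensemble_size >= 2, ensemble_jitter_scale >= 0, feature_snr >= 0,
            sidechain_noise_mult >= 0)
  structure(list(length = as.integer(length), error_segments = error_segments,
                 base_sigma = base_sigma,
                 ensemble_size = as.integer(ensemble_size),
                 ensemble_jitter_scale = ensemble_jitter_scale,
                 feature_snr = feature_snr,
                 sidechain_noise_mult = sidechain_noise_mult, seed = seed),
            class = "synthetic_spec")
}

.residue_sigma <- function(spec) {
  sig <- rep(spec$base_sigma, spec$length)
  seg <- spec$error_segments
  for (k in seq_len(nrow(seg))) {
    idx <- seg$start[k]:seg$end[k]
    sig[idx] <- pmax(sig[idx], seg$sigma[k])
  }
  sig
}

.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

#' Generate a parametric synthetic backbone
#'
#' Builds an idealized protein as consecutive alpha-helical segments
#' (rise 1.5 Angstrom/residue, radius 2.3 Angstrom, 100 degrees/residue)
#' joined by randomly oriented turns, giving consecutive CA-CA distances of
#' about 3.8 Angstrom throughout. Each residue carries dummy heavy backbone
#' atoms (N, C, O) and a CB placed at ideal-ish geometry so all-atom
#' scoring is exercisable. The amino-acid sequence is drawn uniformly.
#' Deterministic per seed.
#'
#' @param L residue count (>= 2).
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return a `structure_model` of length L.
#' @export
make_backbone <- function(L, seed = NULL) {
  stopifnot(L >= 2)
  .maybe_seed(seed)
  rise <- 1.5; radius <- 2.3; omega <- 100 * pi / 180
  # segment lengths 8..14 until L residues are placed
  seg_len <- integer(0)
  left <- L
  while (left > 0) {
    k <- min(left, sample(8:14, 1))
    if (left - k %in% 1:3) k <- left  # avoid stub segments
    seg_len <- c(seg_len, min(k, left))
    left <- left - min(k, left)
  }
  ca <- matrix(0, L, 3)
  pos <- 0L
  origin <- c(0, 0, 0)
  for (s in seq_along(seg_len)) {
    n <- seg_len[s]
    t <- seq_len(n) - 1
    local <- cbind(radius * cos(omega * t), radius * sin(omega * t), rise * t)
    local <- sweep(local, 2, local[1, ])
    R <- .random_rotation()
    seg <- sweep(local %*% t(R), 2, origin, "+")
    ca[pos + seq_len(n), ] <- seg
    pos <- pos + n
    if (pos < L) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      origin <- seg[n, ] + 3.8 * u
    }
  }
  # local frames for placing side atoms
  aa1 <- sample(names(.AA1TO3), L, replace = TRUE)
  rows <- vector("list", L)
  for (i in seq_len(L)) {
    prev <- ca[max(i - 1, 1), ]
    nxt <- ca[min(i + 1, L), ]
    e1 <- nxt - prev
    if (sum(e1^2) < 1e-9) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    ref <- c(0, 0, 1)
    if (abs(sum(ref * e1)) > 0.95) ref <- c(0, 1, 0)
    e2 <- ref - sum(ref * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    p <- ca[i, ]
    xyz <- rbind(N = p - 1.2 * e1 + 0.8 * e2,
                 CA = p,
                 C = p + 1.2 * e1 + 0.6 * e2,
                 O = p + 1.6 * e1 + 1.6 * e2,
                 CB = p - 1.0 * e2 + 1.2 * e3)
    atom_names <- rownames(xyz)
    rownames(xyz) <- NULL
    rows[[i]] <- data.frame(
      resno = i, resid = unname(.AA1TO3[aa1[i]]),
      elety = atom_names,
      element = c("N", "C", "C", "O", "C"),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows), chain_id = "A",
                  sequence = paste(aa1, collapse = ""))
}

#' Generate a decoy with known true LDDT
#'
#' Perturbs every atom of the reference with i.i.d. Gaussian noise whose
#' standard deviation is set per residue by the spec's error segments
#' (residues outside all segments get `base_sigma`), then scores the decoy
#' against the reference so the true LDDT is known exactly. Larger sigma
#' gives stochastically lower segment LDDT.
#'
#' @param reference a `structure_model`.
#' @param spec a [synthetic_spec()] whose `length` matches the reference.
#' @param config [lddt_config()] used for the ground-truth scoring.
#' @param seed integer seed (default `spec$seed`).
#' @return list with `model` (the decoy) and `lddt` (true `lddt_profile`).
#' @export
make_decoy <- function(reference, spec, config = lddt_config(), seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"),
            n_residues(reference) == spec$length)
  .maybe_seed(seed)
  sig <- .residue_sigma(spec)
  at <- reference$atoms
  res_pos <- match(at$resno, residue_indices(reference))
  noise_sd <- sig[res_pos]
  sidechain <- !(at$elety %in% c("N", "CA", "C", "O"))
  noise_sd[sidechain] <- noise_sd[sidechain] * spec$sidechain_noise_mult
  for (cc in c("x", "y", "z")) {
    at[[cc]] <- at[[cc]] + stats::rnorm(nrow(at), sd = noise_sd)
  }
  decoy <- structure_model(at, chain_id = reference$chain_id,
                           sequence = reference$sequence)
  list(model = decoy, lddt = compute_lddt(reference, decoy, config))
}

#' Generate a fluctuating ensemble linked to model error
#'
#' Emulates predictor replicates: each of `ensemble_size` copies of the
#' input model receives per-residue Gaussian jitter with standard deviation
#' proportional to the residue's injected error,
#' `ensemble_jitter_scale * (100 - true_lddt_i) / 100` Angstrom, so poorly
#' modeled residues fluctuate more — the property that makes ensemble RMSF
#' an informative confidence feature.
#'
#' @param reference the `structure_model` to replicate (typically a decoy).
#' @param true_lddt `lddt_profile` or named per-residue vector (0-100).
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (default `spec$seed`).
#' @return an [ensemble()].
#' @export
make_ensemble <- function(reference, true_lddt, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (inherits(true_lddt, "lddt_profile")) true_lddt <- true_lddt$per_residue
  .maybe_seed(seed)
  idx <- residue_indices(reference)
  v <- true_lddt[as.character(idx)]
  v[is.na(v)] <- 100
  sd_res <- spec$ensemble_jitter_scale * (100 - v) / 100
  members <- lapply(seq_len(spec$ensemble_size), function(m) {
    at <- reference$atoms
    noise_sd <- sd_res[match(at$resno, idx)]
    for (cc in c("x", "y", "z")) {
      at[[cc]] <- at[[cc]] + stats::rnorm(nrow(at), sd = noise_sd)
    }
    structure_model(at, chain_id = reference$chain_id,
                    sequence = reference$sequence)
  })
  ensemble(members, reference_member = 1L)
}

#' Generate a feature bundle carrying a controllable quality signal
#'
#' Emulates the opaque feature tensors a structure predictor and a protein
#' language model would provide: all entries are standard Gaussian noise
#' except designated signal slots that carry the (standardized) true LDDT
#' at signal-to-noise ratio `feature_snr` — column 1 of the single
#' representation, column 1 of the language-model embedding (independent
#' noise), and slice 1 of the pair representation (mean of the two
#' endpoint signals). The attention tensor is noise-only. With
#' `feature_snr = 0` every tensor is pure noise (negative control).
#'
#' @param true_lddt `lddt_profile` or numeric per-residue vector (0-100).
#' @param spec a [synthetic_spec()].
#' @param rmsf optional length-L RMSF vector (Angstrom) for the RMSF slot;
#'   default all zero.
#' @param seed integer seed (default `spec$seed`).
#' @return a [feature_bundle()].
#' @export
make_feature_bundle <- function(true_lddt, spec, rmsf = NULL,
                                seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (inherits(true_lddt, "lddt_profile")) true_lddt <- true_lddt$per_residue
  L <- spec$length
  stopifnot(length(true_lddt) == L)
  .maybe_seed(seed)
  v <- as.numeric(true_lddt) / 100
  v[is.na(v)] <- mean(v, na.rm = TRUE)
  z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else rep(0, L)
  snr <- spec$feature_snr
  single <- matrix(stats::rnorm(L * 384), L, 384)
  single[, 1] <- snr * z + stats::rnorm(L)
  esm_embed <- matrix(stats::rnorm(L * 33), L, 33)
  esm_embed[, 1] <- snr * z + stats::rnorm(L)
  pair <- array(stats::rnorm(L * L * 128), c(L, L, 128))
  pair[, , 1] <- snr * outer(z, z, "+") / 2 + matrix(stats::rnorm(L * L), L, L)
  esm_attn <- array(stats::rnorm(L * L * 33), c(L, L, 33))
  if (is.null(rmsf)) rmsf <- rep(0, L)
  rmsf[is.na(rmsf)] <- 0
  feature_bundle(single, pair, esm_embed, esm_attn, rmsf)
}

#' Generate a full synthetic dataset
#'
#' For each protein: a parametric backbone of random length, a decoy with
#' randomized error segments (log-uniform sigma, so all four confidence
#' categories are populated across a dataset), its exact true LDDT, an
#' error-linked ensemble with RMSF, a feature bundle, and the assembled
#' protein graph. All randomness derives from the master seed through a
#' deterministic per-fixture seed stream. Optionally writes the fixtures
#' (reference and decoy PDB, bundle RDS, JSON manifest) to a directory.
#'
#' @param n_proteins number of fixtures.
#' @param length_range inclusive residue-count range (default 40-60; 40 is
#'   the usual minimum chain length for this kind of training data).
#' @param template a [synthetic_spec()] supplying `base_sigma`,
#'   `ensemble_size`, `ensemble_jitter_scale` and `feature_snr` (its
#'   `length`, `error_segments` and `seed` are re-drawn per protein).
#' @param seed master integer seed.
#' @param dir optional output directory for fixture files.
#' @param config [lddt_config()] for ground-truth scoring.
#' @param ablation ablation flags passed to the feature bundles.
#' @param cutoff CA contact cutoff for graph assembly (Angstrom).
#' @return list of records, each with `id`, `reference`, `model`, `lddt`,
#'   `ensemble`, `bundle`, `graph`, `spec`.
#' @export
make_dataset <- function(n_proteins, length_range = c(40, 60),
                         template = synthetic_spec(40), seed = 1,
                         dir = NULL, config = lddt_config(),
                         ablation = list(), cutoff = 16) {
  stopifnot(n_proteins >= 1, length_range[1] >= 2)
  records <- vector("list", n_proteins)
  manifest <- vector("list", n_proteins)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(n_proteins)) {
    s0 <- .seed_stream(seed, 10 * i)
    set.seed(s0)
    lens <- length_range[1]:length_range[2]
    L <- lens[sample.int(length(lens), 1)]
    n_seg <- sample(1:3, 1)
    seg <- data.frame(start = integer(n_seg), end = integer(n_seg),
                      sigma = numeric(n_seg))
    for (k in seq_len(n_seg)) {
      len <- max(4L, as.integer(round(stats::runif(1, 0.15, 0.4) * L)))
      st <- sample(seq_len(max(1L, L - len + 1L)), 1)
      seg$start[k] <- st
      seg$end[k] <- min(L, st + len - 1L)
      seg$sigma[k] <- exp(stats::runif(1, log(0.2), log(5)))
    }
    spec_i <- synthetic_spec(
      length = L, error_segments = seg, base_sigma = template$base_sigma,
      ensemble_size = template$ensemble_size,
      ensemble_jitter_scale = template$ensemble_jitter_scale,
      feature_snr = template$feature_snr, seed = s0)
    reference <- make_backbone(L, seed = .seed_stream(seed, 10 * i + 1))
    dec <- make_decoy(reference, spec_i, config = config,
                      seed = .seed_stream(seed, 10 * i + 2))
    ens <- make_ensemble(dec$model, dec$lddt, spec_i,
                         seed = .seed_stream(seed, 10 * i + 3))
    rmsf <- compute_rmsf(ens)$per_residue[as.character(residue_indices(dec$model))]
    bundle <- make_feature_bundle(dec$lddt, spec_i, rmsf = rmsf,
                                  seed = .seed_stream(seed, 10 * i + 4))
    bundle$ablation <- utils::modifyList(bundle$ablation, ablation)
    graph <- assemble_graph(bundle, ca_coords(dec$model),
                            residue_indices(dec$model), cutoff = cutoff)
    id <- sprintf("synth%03d", i)
    records[[i]] <- list(id = id, reference = reference, model = dec$model,
                         lddt = dec$lddt, ensemble = ens, bundle = bundle,
                         graph = graph, spec = spec_i)
    if (!is.null(dir)) {
      write_annotated_structure(reference, rep(100, L),
                                file.path(dir, paste0(id, "_ref.pdb")))
      lv <- dec$lddt$per_residue
      lv[is.na(lv)] <- 0
      write_annotated_structure(dec$model, lv,
                                file.path(dir, paste0(id, "_model.pdb")))
      write_feature_bundle(bundle, file.path(dir, paste0(id, "_bundle.rds")))
    }
    manifest[[i]] <- list(id = id, length = L, seed = s0,
                          segments = seg, feature_snr = spec_i$feature_snr,
                          ensemble_jitter_scale = spec_i$ensemble_jitter_scale)
  }
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  records
}

#' Convert dataset records into the training format of [qa_head()]
#'
#' @param records output of [make_dataset()].
#' @return list of `list(graph, lddt)` pairs.
#' @export
as_training_set <- function(records) {
  lapply(records, function(r) list(graph = r$graph, lddt = r$lddt))
}
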