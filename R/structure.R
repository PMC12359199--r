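# 3-letter -> 1-letter amino acid codes, plus common modified-residue parents
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.MOD_PARENT <- c(
  MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR", SEC = "CYS",
  PYL = "LYS", HYP = "PRO", MLY = "LYS", CSO = "CYS", KCX = "LYS"
)
.AA1TO3 <- setNames(names(.AA3TO1), unname(.AA3TO1))

#' Construct a structure model
#'
#' A `structure_model` is a single protein chain represented as a table of
#' heavy atoms with 1-based residue indices into an associated sequence.
#' Residue indices strictly increase along the chain; gaps (unresolved
#' residues) are allowed. Every residue carries exactly one CA atom.
#'
#' @param atoms data.frame with columns `resno` (integer residue index),
#'   `resid` (3-letter residue name), `elety` (atom name, e.g. "CA"),
#'   `element` (element symbol), `x`, `y`, `z` (coordinates in Angstrom).
#' @param chain_id chain identifier (single string).
#' @param sequence optional 1-letter sequence string the residue indices
#'   refer to; if `NULL` it is reconstructed from the resolved residues
#'   (unresolved positions are filled with "X").
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms, chain_id = "A", sequence = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("resno", "resid", "elety", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms <- atoms[order(atoms$resno), need, drop = FALSE]
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  rownames(atoms) <- NULL
  resno <- unique(atoms$resno)
  if (any(diff(resno) <= 0)) stop("residue indices must strictly increase")
  ca_per_res <- vapply(split(atoms$elety, atoms$resno),
                       function(e) sum(e == "CA"), integer(1))
  if (any(ca_per_res != 1)) {
    stop("every residue must have exactly one CA atom (offending residues: ",
         paste(resno[ca_per_res != 1], collapse = ", "), ")")
  }
  if (is.null(sequence)) {
    letters1 <- rep("X", max(resno))
    first <- atoms[!duplicated(atoms$resno), ]
    got <- .AA3TO1[first$resid]
    got[is.na(got)] <- "X"
    letters1[first$resno] <- got
    sequence <- paste(letters1, collapse = "")
  }
  structure(list(chain_id = chain_id, atoms = atoms, sequence = sequence),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> chain %s: %d residues, %d heavy atoms\n",
              x$chain_id, length(unique(x$atoms$resno)), nrow(x$atoms)))
  invisible(x)
}

#' Residue indices of a structure model
#' @param model a `structure_model`.
#' @return integer vector of 1-based residue indices, strictly increasing.
#' @export
residue_indices <- function(model) unique(model$atoms$resno)

#' CA coordinates of a structure model
#' @param model a `structure_model`.
#' @return numeric matrix (L x 3) of CA coordinates, rownames = residue index.
#' @export
ca_coords <- function(model) {
  ca <- model$atoms[model$atoms$elety == "CA", ]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
}

n_residues <- function(model) length(unique(model$atoms$resno))

#' Read a protein chain from a PDB file
#'
#' Parses one chain, discards hydrogens and water, keeps the
#' highest-occupancy alternate location (ties broken by altloc letter),
#' maps common modified residues (e.g. MSE) to their standard parent, and
#' drops residues lacking a CA atom (with a message).
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; default `NULL` takes the first chain.
#' @return a `structure_model`.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not found in ", path)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[0-9 ]", "", at$elety), 1, 1)
  }
  at$element <- toupper(trimws(elem))
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  # altloc: keep highest occupancy per (residue, atom name); ties by letter
  at$alt[is.na(at$alt) | at$alt == ""] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  at$.file_ord <- seq_len(nrow(at))
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -occ, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety, sep = "|")), , drop = FALSE]
  at <- at[order(at$.file_ord), , drop = FALSE]  # restore file order
  # modified residues -> standard parent where known, else dropped
  mod <- at$resid %in% names(.MOD_PARENT)
  at$resid[mod] <- .MOD_PARENT[at$resid[mod]]
  unknown <- !(at$resid %in% names(.AA3TO1))
  if (any(unknown)) {
    message("dropping ", length(unique(at$resno[unknown])),
            " non-standard residue(s): ",
            paste(unique(at$resid[unknown]), collapse = ", "))
    at <- at[!unknown, , drop = FALSE]
  }
  # drop residues with no CA
  has_ca <- tapply(at$elety == "CA", at$resno, any)
  bad <- as.integer(names(has_ca))[!has_ca]
  if (length(bad)) {
    message("dropping ", length(bad), " residue(s) with no CA atom: ",
            paste(bad, collapse = ", "))
    at <- at[!(at$resno %in% bad), , drop = FALSE]
  }
  if (nrow(at) == 0) stop("no usable residues in chain '", chain, "'")
  at <- at[order(at$resno, at$.file_ord), , drop = FALSE]
  structure_model(
    data.frame(resno = at$resno, resid = at$resid, elety = at$elety,
               element = at$element, x = at$x, y = at$y, z = at$z,
               stringsAsFactors = FALSE),
    chain_id = chain
  )
}

#' Renumber a structure model against a full sequence
#'
#' Aligns the model's resolved residues to a full 1-letter sequence so that
#' each residue index becomes its 1-based position in that sequence. The
#' alignment is the leftmost exact subsequence embedding; where the original
#' author numbering implies a specific gap length and the embedding is
#' otherwise ambiguous, the author-numbering offset is used to disambiguate.
#'
#' @param model a `structure_model`.
#' @param sequence full-length 1-letter amino-acid string.
#' @return a renumbered `structure_model` whose `sequence` is `sequence`.
#' @export
renumber_to_sequence <- function(model, sequence) {
  seq_chars <- strsplit(sequence, "")[[1]]
  first <- model$atoms[!duplicated(model$atoms$resno), ]
  letters_m <- unname(.AA3TO1[first$resid])
  author <- first$resno
  n <- length(letters_m)

  # leftmost embedding achievable from position p for residues k..n (greedy)
  can_embed <- function(k, p) {
    while (k <= n) {
      hit <- which(seq_chars[p:length(seq_chars)] == letters_m[k])
      if (!length(hit)) return(FALSE)
      p <- p + hit[1]
      k <- k + 1
    }
    TRUE
  }
  pos <- integer(n)
  p <- 1
  for (k in seq_len(n)) {
    cands <- which(seq_chars[p:length(seq_chars)] == letters_m[k]) + p - 1
    if (!length(cands)) stop("model residues cannot be embedded in the sequence")
    choice <- cands[1]
    if (k > 1 && length(cands) > 1) {
      # prefer the candidate matching the author-numbering offset, if viable
      want <- pos[k - 1] + (author[k] - author[k - 1])
      if (want %in% cands && can_embed(k + 1, want + 1)) choice <- want
    }
    if (!can_embed(k + 1, choice + 1)) {
      ok <- cands[vapply(cands, function(cc) can_embed(k + 1, cc + 1), logical(1))]
      if (!length(ok)) stop("model residues cannot be embedded in the sequence")
      choice <- ok[1]
    }
    pos[k] <- choice
    p <- choice + 1
  }
  map <- setNames(pos, author)
  atoms <- model$atoms
  atoms$resno <- unname(map[as.character(atoms$resno)])
  structure_model(atoms, chain_id = model$chain_id, sequence = sequence)
}

#' Write a structure with per-residue scores in the B-factor column
#'
#' Writes a PDB file in which every atom of residue i carries the residue's
#' score (rounded to 2 decimals) in the B-factor column — the convention
#' used for per-residue confidence annotation of predicted structures.
#'
#' @param model a `structure_model`.
#' @param scores an `lddt_profile` or a numeric vector with one value per
#'   residue of `model` (values in \[0, 100\]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotated_structure <- function(model, scores, path) {
  if (inherits(scores, "lddt_profile")) {
    s <- scores$per_residue[as.character(residue_indices(model))]
  } else {
    s <- as.numeric(scores)
    if (length(s) == length(residue_indices(model))) {
      names(s) <- as.character(residue_indices(model))
    } else {
      s <- s[as.character(residue_indices(model))]
    }
  }
  idx <- residue_indices(model)
  if (length(s) != length(idx) || anyNA(s)) {
    stop("scores must provide one defined value per residue of the model")
  }
  if (any(s < 0 | s > 100)) stop("scores must lie in [0, 100]")
  at <- model$atoms
  b <- round(unname(s[as.character(at$resno)]), 2)
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  n <- nrow(at)
  bio3d::write.pdb(
    file = path, xyz = xyz, resno = at$resno, resid = at$resid,
    eleno = seq_len(n), elety = at$elety, chain = rep(model$chain_id, n),
    o = rep(1, n), b = b, elesy = at$element
  )
  invisible(path)
}

#' Read per-residue scores from an annotated structure
#'
#' Recovers the per-residue scores stored in the B-factor column by
#' [write_annotated_structure()] (one value per residue, read from the CA
#' atom).
#'
#' @param path PDB file path.
#' @param chain chain identifier (default first chain).
#' @return an `lddt_profile`.
#' @export
read_annotated_scores <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0) stop("no CA atoms found in chain '", chain, "'")
  new_lddt_profile(setNames(at$b, at$resno))
}
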