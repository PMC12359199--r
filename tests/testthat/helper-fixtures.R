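# fixtures are built in code; nothing binary is stored

# CA-only structure model from a coordinate matrix (or x positions)
ca_model <- function(coords, resno = NULL, resid = "ALA") {
  if (is.null(dim(coords))) coords <- cbind(coords, 0, 0)
  if (is.null(resno)) resno <- seq_len(nrow(coords))
  structure_model(data.frame(
    resno = resno, resid = resid, elety = "CA", element = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# apply a rigid motion to every atom of a structure model
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  at <- model$atoms
  X <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  X <- sweep(X, 2, t, "+")
  at[, c("x", "y", "z")] <- X
  structure_model(at, chain_id = model$chain_id, sequence = model$sequence)
}

# hand-rolled PDB ATOM record writer, independent of the package's writer
write_pdb_fixture <- function(path, atoms) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    name <- if (nchar(a$elety) < 4) sprintf(" %-3s", a$elety) else a$elety
    sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name, a$alt, a$resid, a$chain, a$resno,
            a$x, a$y, a$z, a$o, a$b, a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

default_atom_df <- function(resno, resid, elety, element, x, y, z,
                            chain = "A", alt = "", o = 1, b = 0) {
  data.frame(resno = resno, resid = resid, elety = elety, element = element,
             x = x, y = y, z = z, chain = chain, alt = alt, o = o, b = b,
             stringsAsFactors = FALSE)
}

# small feature bundle with deterministic entries
tiny_bundle <- function(L, seed = 1, ablation = list()) {
  set.seed(seed)
  feature_bundle(
    single = matrix(rnorm(L * 384), L, 384),
    pair = array(rnorm(L * L * 128), c(L, L, 128)),
    esm_embed = matrix(rnorm(L * 33), L, 33),
    esm_attn = array(rnorm(L * L * 33), c(L, L, 33)),
    rmsf = abs(rnorm(L)),
    ablation = ablation)
}

# permute the nodes of a protein graph (for equivariance checks)
permute_graph <- function(graph, perm) {
  inv <- order(perm)
  edges_new <- cbind(inv[graph$edges[, 1]], inv[graph$edges[, 2]])
  ord <- order(edges_new[, 1], edges_new[, 2])
  structure(list(
    coords = graph$coords[perm, , drop = FALSE],
    node_input = graph$node_input[perm, , drop = FALSE],
    edges = edges_new[ord, , drop = FALSE],
    edge_input = graph$edge_input[ord, , drop = FALSE],
    residue_indices = graph$residue_indices[perm],
    ablation = graph$ablation), class = "protein_graph")
}
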