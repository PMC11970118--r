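## shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

test_db <- function() cached("db", synthesize_db(seed = 42))

## glucagon-like 29-residue salt fixture with all 8 coordinated ions
saltbox29 <- function() cached("saltbox29",
                               read_structure(make_fixture("saltbox", 29)))

helix10 <- function() cached("helix10",
                             read_structure(make_fixture("helix", 10)))

## a hand-made building block for unit tests (not from a PDB)
fake_block <- function(names, elements, xyz, kind = "sidechain",
                       resname = "ALA") {
  znum <- unname(blockpol:::.element_z[elements])
  list(block_id = "T:1:test", residue_name = resname, kind = kind,
       chain = "T", resno = 1L, db_key = paste0(resname, ".", kind),
       atoms = data.frame(elety = names, element = elements, znum = znum,
                          x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                          stringsAsFactors = FALSE))
}

## random symmetric positive definite 3x3 tensor
random_spd <- function(lo = 1, hi = 5) {
  r <- blockpol:::random_rotation()
  blockpol:::sym_part(r %*% diag(stats::runif(3, lo, hi)) %*% t(r))
}

## independent assembly of the 3N x 3N relay problem, used as the oracle
## for the ADIM solver (kept deliberately separate from the package's
## internal matrix construction)
oracle_supermatrix <- function(pos, alphas, molecule_id, b = 2.6,
                               damping = "exp") {
  n <- nrow(pos)
  tt <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || identical(molecule_id[i], molecule_id[j])) next
    tij <- field_tensor(pos[i, ], pos[j, ])
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    tij <- thole_damp(tij, r, alphas[[i]], alphas[[j]], b = b,
                      scheme = damping)
    tt[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- tij
  }
  tt
}
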