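test_that("binding respects the distance thresholds", {
  ## isolated sites (single LYS mid-chain plus the termini), so each ion
  ## sees exactly one candidate residue
  seq_iso <- replace(rep("ALA", 15L), 8L, "LYS")

  ## just inside the 2.5 / 3.5 angstrom criteria: Cl- binds LYS and NTER,
  ## Na+ binds CTER
  near <- read_structure(make_fixture("saltbox", 15, sequence = seq_iso,
                                      cl_dist = 2.4, na_dist = 3.4))
  b_near <- detect_bound_ions(near$structure, near$env_sites)
  expect_setequal(b_near$group, c("LYS", "NTER", "CTER"))
  expect_true(all(b_near$distance[b_near$ion_kind == "CL"] <= 2.5))
  expect_true(all(b_near$distance[b_near$ion_kind == "NA"] <= 3.5))

  ## just outside: nothing binds
  far <- read_structure(make_fixture("saltbox", 15, sequence = seq_iso,
                                     cl_dist = 2.6, na_dist = 3.6))
  b_far <- detect_bound_ions(far$structure, far$env_sites)
  expect_equal(nrow(b_far), 0L)
})

test_that("conflicts resolve greedily to the nearest site", {
  x <- saltbox29()
  ## add a second Na+ near an already-occupied ASP, slightly farther out
  at <- x$structure$atoms
  od1 <- unlist(at[at$resno == 24 & trimws(at$elety) == "OD1",
                   c("x", "y", "z")])
  cg <- unlist(at[at$resno == 24 & trimws(at$elety) == "CG",
                  c("x", "y", "z")])
  dir <- (od1 - cg) / sqrt(sum((od1 - cg)^2))
  extra <- od1 + 3.0 * dir + c(0.3, 0, 0)
  env2 <- rbind(x$env_sites,
                data.frame(kind = "NA", x = extra[1], y = extra[2],
                           z = extra[3], charge = 1))
  b <- detect_bound_ions(x$structure, env2)
  ## still one ion per residue: the extra ion stays unbound
  expect_equal(nrow(b), 8L)
  expect_false(anyDuplicated(b$block_id) > 0)
  ## the retained partner of ASP 24 is the closer original ion
  asp24 <- b[grepl("^A:24:", b$block_id), ]
  expect_equal(nrow(asp24), 1L)
  expect_lt(asp24$distance, 2.5)
})

test_that("binding detection is order independent", {
  x <- saltbox29()
  b0 <- detect_bound_ions(x$structure, x$env_sites)
  set.seed(4)
  perm <- sample(nrow(x$env_sites))
  env_p <- x$env_sites[perm, , drop = FALSE]
  rownames(env_p) <- NULL
  bp <- detect_bound_ions(x$structure, env_p)
  ## compare as (block, kind, distance) sets
  key <- function(b) sort(paste(b$block_id, b$ion_kind,
                                round(b$distance, 9)))
  expect_identical(key(bp), key(b0))
})

test_that("neutralization flags bound residues and nothing else", {
  x <- saltbox29()
  ch <- assign_charges(x$structure, ph = 7.3)
  expect_identical(neutralize(ch, detect_bound_ions(
    x$structure, x$env_sites[0, , drop = FALSE])), ch)   # no ions: identity
  b <- detect_bound_ions(x$structure, x$env_sites)
  ch2 <- neutralize(ch, b)
  expect_setequal(ch2$block_id[ch2$neutralized], b$block_id)
  ## with every chargeable residue bound, the +/-1 sites leave the charge
  ## dipole; only the small HIS/TYR fractions remain active
  active <- ch2[!ch2$neutralized, ]
  expect_setequal(active$group, c("HIS", "TYR"))
})

test_that("water cutoff keeps near waters, drops far ones, keeps all ions", {
  x <- helix10()
  at <- x$structure$atoms
  centre <- colMeans(at[, c("x", "y", "z")])
  far_dir <- c(1, 0, 0)
  edge <- at[which.max(at$x), c("x", "y", "z")]
  env <- data.frame(
    kind = c("WATER", "WATER", "NA"),
    x = c(edge$x + 4, edge$x + 30, edge$x + 30),
    y = c(centre[2], centre[2], centre[2]),
    z = c(centre[3], centre[3], centre[3]),
    charge = c(0, 0, 1))
  kept <- ellipsoid_cutoff(x$structure, env, cutoff = 8)
  expect_true(any(kept$kind == "WATER" & kept$x < edge$x + 10))  # near kept
  expect_false(any(kept$kind == "WATER" & kept$x > edge$x + 20)) # far dropped
  expect_true(any(kept$kind == "NA"))                            # ion kept
})

test_that("shrinking the cutoff never adds waters", {
  x <- helix10()
  at <- x$structure$atoms
  set.seed(8)
  n <- 60
  base <- as.matrix(at[sample(nrow(at), n, replace = TRUE), c("x", "y", "z")])
  offs <- matrix(rnorm(3 * n), n, 3) * 6
  env <- data.frame(kind = "WATER", x = base[, 1] + offs[, 1],
                    y = base[, 2] + offs[, 2], z = base[, 3] + offs[, 3],
                    charge = 0)
  wkey <- function(e) paste(round(e$x, 6), round(e$y, 6), round(e$z, 6))
  kept2 <- wkey(ellipsoid_cutoff(x$structure, env, cutoff = 2))
  kept8 <- wkey(ellipsoid_cutoff(x$structure, env, cutoff = 8))
  expect_true(all(kept2 %in% kept8))
  expect_gt(length(kept8), length(kept2))
})

test_that("coplanar geometries fall back to a sphere", {
  grid <- expand.grid(x = seq(0, 10, 2), y = seq(0, 6, 2))
  fake <- list(atoms = data.frame(x = grid$x, y = grid$y, z = 0))
  env <- data.frame(kind = c("WATER", "WATER"),
                    x = c(5, 60), y = c(3, 3), z = c(4, 0),
                    charge = 0)
  kept <- ellipsoid_cutoff(fake, env, cutoff = 8)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$x, 5)
})

test_that("the pair-configuration enumeration matches the combinatorics", {
  cfg <- enumerate_configurations()
  expect_equal(nrow(cfg), 70L)
  expect_equal(unname(table(cfg$n_pairs)), c(1L, 16L, 36L, 16L, 1L),
               ignore_attr = TRUE)
  expect_equal(cfg$number, 1:70)
  expect_false(anyDuplicated(cfg$name) > 0)
  expect_equal(cfg$name[1], "standard")
  expect_equal(cfg$name[70], "ABCDXYZW")
  ## the documented number ranges per pair count
  expect_equal(range(cfg$number[cfg$n_pairs == 1]), c(2L, 17L))
  expect_equal(range(cfg$number[cfg$n_pairs == 2]), c(18L, 53L))
  expect_equal(range(cfg$number[cfg$n_pairs == 3]), c(54L, 69L))
})

test_that("configuration names follow the padded six-character code", {
  expect_equal(config_name(c("A", "C"), c("Z", "W")), "AC-ZW-")
  expect_equal(config_name(character(), character()), "standard")
  expect_equal(config_name(c("A", "B", "C", "D"), c("X", "Y", "Z", "W")),
               "ABCDXYZW")
  ## input order does not matter; Cl letters sort in X,Y,Z,W order
  expect_equal(config_name(c("C", "A"), c("W", "Z")), "AC-ZW-")
  expect_equal(config_name("B", "W"), "B--W--")
  expect_error(config_name(c("A", "B"), "X"), "pairs")
  expect_error(config_name("E", "X"), "invalid")
})
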