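test_that("database JSON round-trips exactly", {
  db <- block_db(list(
    test.block = list(dipole_local = c(0.5, -0.25, 1),
                      polarizability_local = diag(3),
                      frame_atoms = c("N", "CA", "C"))))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_db(db, p1)
  db2 <- load_db(p1)
  expect_equal(db2$entries, db$entries, tolerance = 0)
  save_db(db2, p2)
  expect_identical(readLines(p1), readLines(p2))   # byte-stable

  ## synthetic db round-trip
  p3 <- withr::local_tempfile(fileext = ".json")
  syn <- synthesize_db(seed = 42)
  save_db(syn, p3)
  syn2 <- load_db(p3)
  for (k in names(syn$entries))
    expect_equal(syn2$entries[[k]]$polarizability_local,
                 syn$entries[[k]]$polarizability_local,
                 tolerance = 1e-11)
})

test_that("malformed entries are rejected with the offending key", {
  bad_alpha <- matrix(c(1, 0.2, 0, 0.1, 1, 0, 0, 0, 1), 3, 3)
  expect_error(block_db(list(bad.key = list(
    dipole_local = c(0, 0, 0), polarizability_local = bad_alpha,
    frame_atoms = c("A", "B", "C")))), "bad.key.*not symmetric")
  expect_error(block_db(list(neg.key = list(
    dipole_local = c(0, 0, 0), polarizability_local = -diag(3),
    frame_atoms = c("A", "B", "C")))), "neg.key.*negative eigenvalues")
  expect_error(block_db(list(frame.key = list(
    dipole_local = c(0, 0, 0), polarizability_local = diag(3),
    frame_atoms = c("A", "A", "C")))), "frame.key")
})

test_that("synthetic database is reproducible and well formed", {
  expect_identical(synthesize_db(seed = 1), synthesize_db(seed = 1))
  expect_false(identical(synthesize_db(seed = 1), synthesize_db(seed = 2)))

  db <- test_db()
  for (e in db$entries) {
    ev <- eigen(e$polarizability_local, symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
  ## trace/3 scales with the heavy-atom count
  expect_equal(isotropic_polarizability(
    db$entries[["ALA.sidechain"]]$polarizability_local), 11)   # 1 heavy atom
  expect_equal(isotropic_polarizability(
    db$entries[["ALA.backbone"]]$polarizability_local), 44)    # N, CA, C, O

  iso_db <- synthesize_db(seed = 5, anisotropy_frac = 0)
  for (e in iso_db$entries)
    expect_lt(polarizability_anisotropy(e$polarizability_local), 1e-9)
})

test_that("placement rotates properties by the anchor frame", {
  entry <- list(dipole_local = c(1, 0, 0),
                polarizability_local = diag(c(1, 2, 3)),
                frame_atoms = c("A1", "A2", "A3"))
  ## frame aligned with the global axes: identity placement
  blk <- fake_block(c("A1", "A2", "A3"), c("C", "C", "C"),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  p <- place_entry(entry, blk)
  expect_equal(p$dipole, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(p$alpha, diag(c(1, 2, 3)), tolerance = 1e-12)

  ## frame rotated 90 degrees about z: diag(1,2,3) -> diag(2,1,3)
  blk90 <- fake_block(c("A1", "A2", "A3"), c("C", "C", "C"),
                      rbind(c(0, 0, 0), c(0, 1, 0), c(-1, 0, 0)))
  p90 <- place_entry(entry, blk90)
  expect_equal(p90$alpha, diag(c(2, 1, 3)), tolerance = 1e-12)
  expect_equal(p90$dipole, c(0, 1, 0), tolerance = 1e-12)
})

test_that("placement preserves eigenvalues under random rotations", {
  set.seed(21)
  entry <- list(dipole_local = c(0.3, -0.7, 0.1),
                polarizability_local = random_spd(),
                frame_atoms = c("A1", "A2", "A3"))
  base <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0.5, 1.2, 0))
  ev0 <- sort(eigen(entry$polarizability_local, symmetric = TRUE,
                    only.values = TRUE)$values)
  for (k in 1:10) {
    r <- blockpol:::random_rotation()
    blk <- fake_block(c("A1", "A2", "A3"), c("C", "C", "C"),
                      base %*% t(r))
    p <- place_entry(entry, blk)
    ev <- sort(eigen(p$alpha, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(ev, ev0, tolerance = 1e-12)
    expect_equal(sqrt(sum(p$dipole^2)), sqrt(sum(entry$dipole_local^2)),
                 tolerance = 1e-12)
  }
})

test_that("collinear or missing frame atoms are an error", {
  entry <- list(dipole_local = c(1, 0, 0), polarizability_local = diag(3),
                frame_atoms = c("A1", "A2", "A3"))
  collinear <- fake_block(c("A1", "A2", "A3"), c("C", "C", "C"),
                          rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(place_entry(entry, collinear), "collinear")
  missing_ <- fake_block(c("A1", "A2", "B9"), c("C", "C", "C"),
                         rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_error(place_entry(entry, missing_), "A3")
})
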