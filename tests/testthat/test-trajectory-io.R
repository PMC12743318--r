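test_that("PDB topology round-trip preserves residue structure and serials", {
  ch <- build_pet_chain(2, conformer_mixture(), seed = 4)
  tr <- toy_trajectory(ch$coords, topology = ch$topology)
  f <- tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  top2 <- read_topology(f)
  expect_equal(top2$n_atoms, ch$topology$n_atoms)
  expect_equal(top2$atoms$name, ch$topology$atoms$name)
  expect_equal(top2$atoms$resid, ch$topology$atoms$resid)
  expect_equal(top2$atoms$resname, ch$topology$atoms$resname)
})

test_that("duplicate serials are rejected", {
  atoms <- data.frame(serial = c(1, 1, 2), name = "C1", resname = "UNK",
                      resid = 1:3, segid = "X")
  expect_error(pet_topology(atoms), "duplicated")
})

test_that("PSF atoms resolve by (resname, resid, name) address", {
  psf <- tempfile(fileext = ".psf")
  writeLines(c("PSF", "", "       1 !NTITLE", "REMARKS x", "",
               "       2 !NATOM",
               "       1 PROT 156  SER  OG   OG1   -0.66  15.999  0",
               "       2 PROT 234  HIS  NE2  NR1   -0.70  14.007  0"), psf)
  top <- read_topology(psf)
  expect_equal(top$n_atoms, 2)
  sel <- select_atoms(top, "resid 156 and name OG")
  expect_equal(length(sel$indices), 1)
  expect_equal(top$atoms$resname[sel$indices], "SER")
  expect_equal(top$atoms$segid, c("PROT", "PROT"))
})

test_that("malformed PSF records name the offending line", {
  psf <- tempfile(fileext = ".psf")
  writeLines(c("PSF", "", "       2 !NATOM",
               "       1 PROT 156  SER  OG   OG1   -0.66  15.999  0",
               "       2 PROT badresid"), psf)
  expect_error(read_topology(psf), "line 5")
})

test_that("DCD and multi-model PDB round-trip coordinates and box", {
  ch <- build_pet_chain(2, conformer_mixture(), seed = 5)
  xyz <- rbind(as.vector(t(ch$coords)), as.vector(t(ch$coords)) + 0.25)
  tr <- pet_trajectory(ch$topology, xyz, box = c(40, 50, 60))
  for (fmt in c("dcd", "pdb")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_trajectory(tr, f)
    tr2 <- read_trajectory(f, ch$topology)
    expect_equal(n_frames(tr2), 2)
    expect_lt(max(abs(tr2$xyz - tr$xyz)), 1e-3)
    expect_equal(tr2$box[1, ], c(40, 50, 60), tolerance = 1e-6)
  }
})

test_that("stride keeps ceiling(n/s) frames in file order", {
  ch <- build_pet_chain(1, conformer_mixture(), seed = 6)
  n <- 10
  xyz <- matrix(rep(as.vector(t(ch$coords)), n), n, byrow = TRUE) + seq_len(n)
  f <- tempfile(fileext = ".dcd")
  write_trajectory(pet_trajectory(ch$topology, xyz, box = c(30, 30, 30)), f)
  for (s in c(1, 2, 3, 4)) {
    trs <- read_trajectory(f, ch$topology, stride = s)
    expect_equal(n_frames(trs), ceiling(n / s))
    expect_equal(trs$xyz[2, 1], xyz[1 + s, 1], tolerance = 1e-4)
  }
})

test_that("atom-count mismatch is a hard error, truncated frame a warning", {
  ch <- build_pet_chain(1, conformer_mixture(), seed = 7)
  xyz <- matrix(rep(as.vector(t(ch$coords)), 3), 3, byrow = TRUE)
  f <- tempfile(fileext = ".dcd")
  write_trajectory(pet_trajectory(ch$topology, xyz, box = c(30, 30, 30)), f)
  expect_error(read_trajectory(f, toy_topology(10)), "does not match")
  raw <- readBin(f, "raw", file.size(f) - 50)
  f2 <- tempfile(fileext = ".dcd")
  writeBin(raw, f2)
  expect_warning(tr2 <- read_trajectory(f2, ch$topology), "truncated")
  expect_equal(n_frames(tr2), 2)
})

test_that("empty and box-less writes behave as documented", {
  ch <- build_pet_chain(1, conformer_mixture(), seed = 8)
  tr <- pet_trajectory(ch$topology, matrix(as.vector(t(ch$coords)), 1))
  # an empty trajectory cannot even be constructed
  expect_error(pet_trajectory(ch$topology,
                              matrix(numeric(0), 0, 3 * ch$topology$n_atoms)),
               "at least one frame")
  f <- tempfile(fileext = ".dcd")
  expect_warning(write_trajectory(tr, f), "zero cell")
  tr2 <- read_trajectory(f, ch$topology)
  expect_null(tr2$box)
})

test_that("selection language matches by composition and is idempotent", {
  m <- build_melt(5, 9, seed = 9, box = c(80, 80, 80))
  top <- m$topology
  est <- select_atoms(top, "segid PET and name C1 C8")
  expect_equal(length(est$indices), 5 * 9 * 2)
  expect_equal(length(select_atoms(top, "all")$indices), top$n_atoms)
  # idempotence and distribution over union/intersection
  a <- select_atoms(top, "name C1")$indices
  b <- select_atoms(top, "name C8")$indices
  expect_equal(select_atoms(top, "name C1 or name C8")$indices,
               sort(union(a, b)))
  expect_equal(select_atoms(top, "(name C1 C8) and chain 2")$indices,
               intersect(est$indices, select_atoms(top, "chain 2")$indices))
  expect_equal(select_atoms(top, "not not name C1")$indices, a)
})

test_that("selection errors carry position; empty selections are not errors", {
  top <- toy_topology(3)
  expect_error(select_atoms(top, "name C1 and"), "token")
  expect_error(select_atoms(top, "resid x"), "resid")
  expect_message(s <- select_atoms(top, "resname XYZ"), "no atoms")
  expect_equal(length(s$indices), 0)
})
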