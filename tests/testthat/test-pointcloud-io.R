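test_that("ap_fraction rescales the principal axis to [0,1]", {
  nuc <- tibble::tibble(nucleus_id = 1:3, x = c(0, 125, 250),
                        y = c(0, 1, 0), z = c(0, 0, 1), lacZ = c(1, 2, 3))
  emb <- embryo(nuc, embryo_id = "e")
  expect_equal(emb$nuclei$ap_fraction, c(0, 0.5, 1), tolerance = 1e-3)
})

test_that("reading the hand-written fixture reproduces its literal values", {
  emb <- read_pointcloud(test_path("fixture-pointcloud.txt"))
  expect_s3_class(emb, "embryo")
  expect_equal(emb$embryo_id, "fix01")
  expect_equal(emb$genotype, "minWT")
  expect_equal(emb$stain_id, "stainA")
  expect_equal(emb$stage_pct, 6)
  expect_setequal(channels(emb), c("lacZ", "hkb", "ftz"))
  expect_equal(emb$nuclei$lacZ, c(1.5, 2.25, 7.5, 3, 0.5))
  expect_equal(emb$nuclei$hkb, c(0.2, 0.4, 0.1, 0.8, 6))
  expect_equal(emb$nuclei$ftz, c(3, 2.5, 0, 1.25, 0.75))
  expect_equal(emb$nuclei$x, c(0, 60, 125, 190, 250))
  # anterior = lowest x, posterior = highest x
  expect_equal(emb$nuclei$ap_fraction[1], 0)
  expect_equal(emb$nuclei$ap_fraction[5], 1)
})

test_that("write_pointcloud / read_pointcloud round-trip is the identity", {
  cfg <- reporter_config(n_nuclei = 150, nucleus_noise_sigma = 0.3,
                         outlier_rate = 0)
  emb <- generate_embryo(cfg, "A", seed = 9)
  path <- withr::local_tempfile(fileext = ".txt")
  write_pointcloud(emb, path)
  back <- read_pointcloud(path)
  expect_equal(back$embryo_id, emb$embryo_id)
  expect_equal(back$genotype, emb$genotype)
  expect_equal(back$stain_id, emb$stain_id)
  expect_equal(back$stage_pct, emb$stage_pct)
  for (col in names(emb$nuclei)) {
    expect_equal(back$nuclei[[col]], emb$nuclei[[col]], tolerance = 1e-9,
                 label = col)
  }
})

test_that("PointCloud format errors name the offending column or line", {
  bad_col <- withr::local_tempfile(lines = c(
    "# embryo_id=e", "# columns=nucleus_id,x,y,lacZ", "1,0,0,1"))
  expect_error(read_pointcloud(bad_col), "z")

  bad_cell <- withr::local_tempfile(lines = c(
    "# embryo_id=e", "# columns=nucleus_id,x,y,z,lacZ",
    "1,0,0,0,1", "2,10,0,0,oops", "3,20,1,1,2"))
  expect_error(read_pointcloud(bad_cell), "line 4")

  dup <- withr::local_tempfile(lines = c(
    "# embryo_id=e", "# columns=nucleus_id,x,y,z,lacZ",
    "1,0,0,0,1", "1,10,2,0,2", "3,20,0,3,2"))
  expect_error(read_pointcloud(dup), "duplicate nucleus_id")

  no_chan <- withr::local_tempfile(lines = c(
    "# columns=nucleus_id,x,y,z", "1,0,0,0"))
  expect_error(read_pointcloud(no_chan), "channel")
})

test_that("ap_fraction is invariant under translation and uniform scaling", {
  cfg <- reporter_config(n_nuclei = 200, outlier_rate = 0)
  emb <- generate_embryo(cfg, "A", seed = 3)
  nuc <- emb$nuclei[c("nucleus_id", "x", "y", "z")]
  nuc$lacZ <- emb$nuclei$lacZ
  moved <- nuc
  moved$x <- 3.1 * moved$x + 500
  moved$y <- 3.1 * moved$y - 40
  moved$z <- 3.1 * moved$z + 7
  e1 <- embryo(nuc, embryo_id = "a")
  e2 <- embryo(moved, embryo_id = "b")
  expect_equal(e2$nuclei$ap_fraction, e1$nuclei$ap_fraction, tolerance = 1e-9)
  expect_equal(e2$nuclei$dv_angle, e1$nuclei$dv_angle, tolerance = 1e-9)
})

test_that("FASTA reading handles simple, wrapped and invalid records", {
  fa <- withr::local_tempfile(lines = c(">s", "ACGT"))
  expect_equal(read_fasta(fa)$sequence, "ACGT")

  wrapped <- withr::local_tempfile(lines = c(">w", "ACGTAC", "GTTTTT", "AA"))
  out <- read_fasta(wrapped)
  expect_equal(out$sequence, "ACGTACGTTTTTAA")
  expect_equal(out$width, 14L)
})

test_that("FASTA write/read round-trips random sequences", {
  set.seed(42)
  for (i in 1:8) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:200, 1), TRUE),
               collapse = "")
    path <- withr::local_tempfile(fileext = ".fa")
    write_fasta(tibble::tibble(name = "r", sequence = s), path)
    expect_equal(read_fasta(path)$sequence, s)
  }
})

test_that("bundled synthetic enhancer fixtures have the construct lengths", {
  fa <- read_fasta(system.file("extdata", "synthetic_enhancers.fa",
                               package = "stripequant"))
  expect_equal(fa$width[fa$name == "minWT_synthetic"], 484L)
  expect_equal(fa$width[fa$name == "extWT_synthetic"], 798L)
})

test_that("PWM reading enforces the format and reorders labelled rows", {
  p1 <- withr::local_tempfile(lines = c("A 10 0 5", "C 0 10 5",
                                        "G 0 0 5", "T 2 1 5"))
  pwm <- read_pwm(p1)
  expect_s3_class(pwm, "pwm_matrix")
  expect_equal(pwm$width, 3L)
  expect_equal(unname(colSums(pwm$counts)), c(12, 11, 20))

  # rows out of order are reordered by their labels
  p2 <- withr::local_tempfile(lines = c("C 0 10", "A 10 0", "T 2 1", "G 0 0"))
  pwm2 <- read_pwm(p2)
  expect_equal(unname(pwm2$counts["A", ]), c(10, 0))
  expect_equal(unname(pwm2$counts["C", ]), c(0, 10))

  # single-column matrix
  p3 <- withr::local_tempfile(lines = c("A 10", "C 0", "G 0", "T 0"))
  expect_equal(read_pwm(p3)$width, 1L)

  uneq <- withr::local_tempfile(lines = c("A 1 2", "C 1", "G 1 2", "T 1 2"))
  expect_error(read_pwm(uneq), "unequal")
  neg <- withr::local_tempfile(lines = c("A 1", "C -1", "G 1", "T 1"))
  expect_error(read_pwm(neg), "negative")
})
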