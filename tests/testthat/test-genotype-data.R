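# Data model, table/GENEPOP I/O, allele frequencies, distances.

test_that("CSV genotype tables parse, normalise missing data and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,stage,x,y,cwd_id,dbh,age,GC1_1,GC1_2,GD1_1,GD1_2",
    "a1,mature,0,0,,35,,100,102,140,140",
    "a2,mature,3,4,,22,,100,100,142,144",
    "a3,seedling,1,1,L7,,2,102,102,0,140",
    "a4,sapling,2,2,L7,,5,100,102,,"), tmp)
  ds <- read_genotype_table(tmp)
  expect_equal(n_individuals(ds), 4)
  expect_equal(locus_names(ds), c("GC1", "GD1"))
  # one-sided missing allele (a3 at GD1) makes the whole locus missing
  expect_true(is.na(ds$a1[3, "GD1"]) && is.na(ds$a2[3, "GD1"]))
  expect_true(is.na(ds$a1[4, "GD1"]))
  expect_equal(ds$info$cwd_id[3], "L7")

  out <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(ds, out)
  ds2 <- read_genotype_table(out)
  expect_identical(ds2$a1, ds$a1)
  expect_identical(ds2$a2, ds$a2)
  expect_equal(ds2$info, ds$info)
})

test_that("malformed rows and unknown stages are rejected with location info", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,stage,x,y,L1_1,L1_2",
               "a,mature,0,0,100,xx"), tmp)
  expect_error(read_genotype_table(tmp), "L1_2.*row 1")
  writeLines(c("id,stage,x,y,L1_1,L1_2",
               "a,tree,0,0,100,102"), tmp)
  expect_error(read_genotype_table(tmp), "stage")
})

test_that("dataset invariants are enforced", {
  geno <- list(list(L1 = c(1, 2)), list(L1 = c(1, 1)))
  expect_error(make_ds(geno, stage = "mature", dbh = c(15, 30)), "dbh")
  expect_error(make_ds(geno, stage = "juvenile", dbh = c(25, 10)), "dbh")
  ds <- make_ds(geno, stage = c("seedling", "mature"))
  expect_s3_class(ds, "genotype_dataset")
  info <- ds$info; info$cwd_id <- NA
  expect_error(genotype_dataset(info, ds$a1, ds$a2), "cwd_id")
  info2 <- ds$info; info2$id <- c("x", "x")
  expect_error(genotype_dataset(info2, ds$a1, ds$a2), "unique")
})

test_that("GENEPOP round-trips genotypes, stages and missing data", {
  set.seed(42)
  ds <- random_hwe_ds(12, equifreqs(3, 4), stage = rep(c("mature", "juvenile"),
                                                       each = 6))
  ds$a1[2, 1] <- ds$a2[2, 1] <- NA
  gp <- withr::local_tempfile(fileext = ".gen")
  write_genepop(ds, gp)
  side <- ds$info[, c("id", "x", "y", "cwd_id", "dbh", "age")]
  ds2 <- read_genepop(gp, pop_stages = c("juvenile", "mature"), coords = side)
  # GENEPOP groups by stage; realign by id
  m <- match(ds$info$id, ds2$info$id)
  expect_equal(ds2$a1[m, ], ds$a1, ignore_attr = TRUE)
  expect_equal(ds2$a2[m, ], ds$a2, ignore_attr = TRUE)
  expect_equal(ds2$info$stage[m], ds$info$stage)
  expect_equal(ds2$info$x[m], ds$info$x)
})

test_that("GENEPOP conventions: 0000 is missing, bad widths are format errors", {
  gp <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "locA", "locB", "POP",
               "i1 , 0102 0000",
               "i2 , 0101 0304",
               "POP",
               "i3 , 0202 0303"), gp)
  ds <- read_genepop(gp, pop_stages = c("mature", "sapling"),
                     coords = data.frame(id = c("i1", "i2", "i3"),
                                         x = 1:3, y = 1:3,
                                         cwd_id = c(NA, NA, "L1")))
  expect_equal(sort(unique(ds$info$stage)), c("mature", "sapling"))
  expect_true(is.na(ds$a1[1, "locB"]))
  expect_equal(ds$a1[2, "locB"], 3L)
  writeLines(c("toy", "locA", "POP", "i1 , 01023"), gp)
  expect_error(read_genepop(gp), "width")
})

test_that("allele frequencies match a brute-force tally and flag empty loci", {
  ds <- make_ds(list(list(L1 = c(1, 1), L2 = c(5, 6)),
                     list(L1 = c(1, 1), L2 = c(5, 5)),
                     list(L1 = c(1, 1))))
  af <- allele_frequencies(ds)
  expect_equal(af$freqs$L1, c("1" = 1.0))
  expect_equal(af$n[["L1"]], 6)
  expect_equal(af$freqs$L2, c("5" = 0.75, "6" = 0.25))
  expect_equal(af$n[["L2"]], 4)

  set.seed(7)
  big <- random_hwe_ds(40, equifreqs(4, 6))
  idx <- sample(40, 10)
  big$a1[idx, 2] <- NA; big$a2[idx, 2] <- NA
  af2 <- allele_frequencies(big)
  for (l in locus_names(big)) {
    g <- c(big$a1[, l], big$a2[, l]); g <- g[!is.na(g)]
    tab <- table(g) / length(g)
    expect_equal(af2$freqs[[l]], c(tab)[names(af2$freqs[[l]])],
                 tolerance = 1e-12)
    expect_equal(af2$n[[l]], length(g))
  }
  empty <- big; empty$a1[, 1] <- NA; empty$a2[, 1] <- NA
  expect_warning(allele_frequencies(empty), "excluded")
})

test_that("pairwise distances are Euclidean, symmetric, zero-diagonal", {
  ds <- make_ds(list(list(L1 = c(1, 2)), list(L1 = c(1, 2))),
                x = c(0, 3), y = c(0, 4))
  D <- pairwise_distances(ds)
  expect_equal(D[1, 2], 5)
  expect_equal(diag(D), c(I01 = 0, I02 = 0))
  set.seed(3)
  ds2 <- random_hwe_ds(15, equifreqs(1, 3))
  D2 <- pairwise_distances(ds2)
  expect_equal(D2, t(D2))
  i <- 4; j <- 11
  expect_equal(D2[i, j], sqrt((ds2$info$x[i] - ds2$info$x[j])^2 +
                                (ds2$info$y[i] - ds2$info$y[j])^2))
})
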