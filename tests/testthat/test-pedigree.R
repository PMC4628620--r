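test_that("pedigree validation orders parents before children and counts founders", {
  ped <- ped_trio()
  expect_s3_class(ped, "pedigree")
  expect_equal(attr(ped, "n_founders"), 2L)
  expect_equal(ped$id, c("F", "M", "C"))

  ped20 <- small_random_ped(seed = 7, n_founders = 8)
  idx <- seq_len(nrow(ped20)); names(idx) <- ped20$id
  nonf <- !is.na(ped20$father)
  expect_true(all(idx[ped20$father[nonf]] < idx[ped20$id[nonf]]))
  expect_true(all(idx[ped20$mother[nonf]] < idx[ped20$id[nonf]]))
  # exhaustive ancestor scan: no individual reachable from itself
  anc_of <- function(i) {
    out <- integer(0); queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      p <- c(idx[ped20$father[v]], idx[ped20$mother[v]])
      p <- p[!is.na(p)]
      out <- union(out, p); queue <- c(queue, p)
    }
    out
  }
  for (i in seq_len(nrow(ped20))) expect_false(i %in% anc_of(i))
})

test_that("structural defects are rejected with specific errors", {
  expect_error(pedigree("C", "C", "M", 1), "parent")            # missing M too
  expect_error(pedigree(c("C", "M"), c("C", "0"), c("M", "0"), c(1, 2)),
               "cycle")
  expect_error(pedigree(c("C", "M"), c("F", "0"), c("M", "0"), c(1, 2)),
               "absent")
  expect_error(pedigree(c("C", "F"), c("F", "0"), c("0", "0"), c(1, 1)),
               "half-specified")
  expect_error(pedigree(c("A", "A"), c("0", "0"), c("0", "0"), c(1, 1)),
               "duplicated")
  # deeper cycle: A -> B -> A
  expect_error(pedigree(c("A", "B", "Z"), c("B", "A", "0"), c("Z", "Z", "0"),
                        c(1, 1, 2)), "cycle")
})

test_that("kinship recursion reproduces textbook coefficients", {
  kin <- kinship(ped_trio())
  expect_equal(kin$phi["F", "C"], 0.25)
  expect_equal(kin$phi["F", "M"], 0)
  expect_equal(unname(kin$F), rep(0, 3))

  ks <- kinship(ped_sibs())
  expect_equal(ks$phi["S1", "S2"], 0.25)
  expect_equal(ks$phi["S1", "S1"], 0.5)

  kc <- kinship(ped_cousin_child())
  expect_equal(kc$phi["X", "Y"], 0.0625)   # first cousins
  expect_equal(unname(kc$F["Z"]), 0.0625)  # child of first-cousin mating
  expect_equal(kc$phi["Z", "Z"], 0.5 * (1 + 0.0625))
})

test_that("kinship matrix is symmetric PSD and founder-independent on random pedigrees", {
  for (s in 1:5) {
    ped <- small_random_ped(seed = s)
    kin <- kinship(ped)
    expect_identical(kin$phi, t(kin$phi))
    expect_true(all(kin$phi >= 0 & kin$phi <= 1))
    expect_true(all(diag(kin$phi) >= 0.5 & diag(kin$phi) <= 1))
    expect_gte(min(eigen(2 * kin$phi, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
    # founders have kinship 0 with everyone outside their own descendants
    desc <- function(id) {
      out <- id
      repeat {
        more <- ped$id[ped$father %in% out | ped$mother %in% out]
        if (all(more %in% out)) break
        out <- union(out, more)
      }
      out
    }
    founders <- ped$id[is.na(ped$father)]
    for (f in founders[1:3]) {
      others <- setdiff(ped$id, desc(f))
      if (length(others)) expect_true(all(kin$phi[f, others] == 0))
    }
  }
})

test_that("row order permutation leaves kinship unchanged up to relabeling", {
  ped <- small_random_ped(seed = 11)
  kin <- kinship(ped)
  set.seed(1)
  perm <- sample(nrow(ped))
  df <- as.data.frame(ped)[perm, ]
  df$father[is.na(df$father)] <- "0"
  df$mother[is.na(df$mother)] <- "0"
  kin2 <- kinship(validate_pedigree(df))
  expect_equal(kin2$phi[kin$ids, kin$ids], kin$phi)
})

test_that("inbreeding classes split zero and nonzero coefficients as specified", {
  expect_equal(as.character(inbreeding_classes(c(0, 0, 0, 0))),
               rep("C0", 4))
  expect_equal(as.character(inbreeding_classes(c(0, 0.01, 0.02, 0.03, 0.04))),
               c("C0", "Q1", "Q2", "Q3", "Q4"))
  expect_error(inbreeding_classes(c(-0.1, 0)), "non-negative")

  set.seed(42)
  F <- c(rep(0, 400), rexp(600, rate = 50))
  cls <- inbreeding_classes(F)
  expect_equal(unname(table(cls)["C0"]), 400, ignore_attr = TRUE)
  # direct percentile oracle on the nonzero subset
  qs <- quantile(F[F > 0], c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(sum(cls == "Q1"), sum(F > 0 & F <= qs[1]))
  expect_equal(sum(cls == "Q2"), sum(F > qs[1] & F <= qs[2]))
  expect_equal(as.vector(table(cls)[paste0("Q", 1:4)]), rep(150, 4))
  # value exactly on the 25th percentile goes to the lower class
  expect_equal(as.character(inbreeding_classes(c(1, 2, 3, 4, 5))[2]), "Q1")
})

test_that("fam round-trip preserves the pedigree", {
  ped <- small_random_ped(seed = 3)
  tmp <- withr::local_tempfile(fileext = ".fam")
  write_fam(ped, tmp)
  ped2 <- read_fam(tmp)
  expect_equal(as.data.frame(ped2), as.data.frame(ped))
  # header detection
  writeLines(c("FID IID FATHER MOTHER SEX PHENO",
               "F1 A 0 0 1 -9", "F1 B 0 0 2 -9", "F1 C A B 1 -9"), tmp)
  ped3 <- read_fam(tmp)
  expect_equal(nrow(ped3), 3)
  expect_equal(attr(ped3, "n_founders"), 2L)
})

test_that("kinship writers emit long and matrix formats", {
  kin <- kinship(ped_trio())
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_kinship(kin, tmp, format = "long")
  lg <- read.delim(tmp)
  expect_true(any(lg$id1 == "F" & lg$id2 == "C" & lg$phi == 0.25))
  write_kinship(kin, tmp, format = "matrix")
  mt <- read.delim(tmp, check.names = FALSE)
  expect_equal(mt[["C"]][mt$id == "F"], 0.25)
})
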