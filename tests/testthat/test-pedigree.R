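test_that("parse_pedigree orders parents before offspring and adds implicit founders", {
  ped <- parse_pedigree(data.frame(id = c("C", "A", "B"),
                                   sire = c("A", "0", "0"),
                                   dam = c("B", "0", "0")))
  expect_equal(ped$n, 3L)
  expect_equal(ped$id[3], "C")
  expect_true(all(is.na(ped$sire[1:2])))

  # animal referenced only as a parent becomes a founder
  ped2 <- parse_pedigree(data.frame(id = "X", sire = "S", dam = "0"))
  expect_equal(sort(ped2$id), c("S", "X"))
  expect_true(is.na(ped2$sire[ped2$id == "S"]))

  # child listed before parent in the file is reordered
  ped3 <- parse_pedigree(data.frame(id = c("kid", "pa", "ma"),
                                    sire = c("pa", "0", "0"),
                                    dam = c("ma", "0", "0")))
  expect_equal(ped3$id[3], "kid")
  for (i in seq_len(ped3$n)) {
    for (p in c(ped3$sire[i], ped3$dam[i]))
      if (!is.na(p)) expect_lt(p, i)
  }
})

test_that("parse_pedigree rejects cycles and duplicate ids", {
  expect_error(parse_pedigree(data.frame(id = "X", sire = "X", dam = "0")),
               "cycle")
  expect_error(parse_pedigree(data.frame(id = c("A", "B"),
                                         sire = c("B", "A"),
                                         dam = c("0", "0"))),
               "cycle")
  expect_error(parse_pedigree(data.frame(id = c("A", "A"),
                                         sire = c("0", "0"),
                                         dam = c("0", "0"))),
               "duplicate")
})

test_that("inbreeding matches known closed-form cases", {
  # all founders
  ped <- parse_pedigree(data.frame(id = letters[1:4], sire = "0", dam = "0"))
  expect_equal(unname(inbreeding(ped)), rep(0, 4))

  # offspring of two full sibs: F = 0.25
  ped <- parse_pedigree(data.frame(id = c("a", "b", "s1", "s2", "x"),
                                   sire = c("0", "0", "a", "a", "s1"),
                                   dam = c("0", "0", "b", "b", "s2")))
  expect_equal(unname(inbreeding(ped)["x"]), 0.25)

  # offspring of paternal half sibs: F = 0.125
  ped <- parse_pedigree(data.frame(id = c("s", "d1", "d2", "h1", "h2", "y"),
                                   sire = c("0", "0", "0", "s", "s", "h1"),
                                   dam = c("0", "0", "0", "d1", "d2", "h2")))
  expect_equal(unname(inbreeding(ped)["y"]), 0.125)
})

test_that("inbreeding is invariant to input row order", {
  set.seed(41)
  ped <- random_pedigree(60, founder_frac = 0.2)
  tab <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$id[ped$sire]),
                    dam = ifelse(is.na(ped$dam), "0", ped$id[ped$dam]))
  shuf <- tab[sample.int(nrow(tab)), ]
  F1 <- inbreeding(parse_pedigree(tab))
  F2 <- inbreeding(parse_pedigree(shuf))
  expect_equal(F1[sort(names(F1))], F2[sort(names(F2))])
})

test_that("relationship_matrix reproduces textbook relationships", {
  # unrelated founders -> identity
  ped <- parse_pedigree(data.frame(id = letters[1:5], sire = "0", dam = "0"))
  expect_equal(unname(relationship_matrix(ped)), diag(5))

  # parent-offspring additive relationship 0.5 (checked against a
  # gene-dropping Monte Carlo kinship oracle)
  ped <- parse_pedigree(data.frame(id = c("p", "q", "o"),
                                   sire = c("0", "0", "p"),
                                   dam = c("0", "0", "q")))
  A <- relationship_matrix(ped)
  expect_equal(A["p", "o"], 0.5)
  set.seed(7)
  expect_equal(gene_drop_relationship(ped, 1, 3, reps = 4000), 0.5,
               tolerance = 0.05)

  # full sibs 0.5; their offspring's diagonal 1.25
  ped <- parse_pedigree(data.frame(id = c("a", "b", "s1", "s2", "x"),
                                   sire = c("0", "0", "a", "a", "s1"),
                                   dam = c("0", "0", "b", "b", "s2")))
  A <- relationship_matrix(ped)
  expect_equal(A["s1", "s2"], 0.5)
  expect_equal(A["x", "x"], 1.25)
  expect_error(relationship_matrix(ped, max_n = 3), "a_inverse")
})

test_that("inbreeding equals diag(A) - 1 on random pedigrees (independent paths)", {
  set.seed(11)
  for (rep in 1:20) {
    ped <- random_pedigree(sample(20:120, 1), founder_frac = runif(1, 0.1, 0.5))
    A <- relationship_matrix(ped)
    expect_equal(unname(diag(A) - 1), unname(inbreeding(ped)),
                 tolerance = 1e-12)
  }
})

test_that("A is symmetric positive semi-definite on random pedigrees", {
  set.seed(13)
  for (rep in 1:5) {
    ped <- random_pedigree(150, founder_frac = 0.25)
    A <- relationship_matrix(ped)
    expect_equal(A, t(A))
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("sparse A-inverse matches the dense inverse", {
  # founders only -> identity
  ped <- parse_pedigree(data.frame(id = letters[1:4], sire = "0", dam = "0"))
  expect_equal(as.matrix(a_inverse(ped)), diag(4), ignore_attr = TRUE)

  set.seed(17)
  # random pedigrees, with and without inbreeding
  for (rep in 1:10) {
    ped <- random_pedigree(50, founder_frac = 0.3)
    A <- relationship_matrix(ped)
    Ai <- as.matrix(a_inverse(ped))
    expect_lt(max(abs(Ai %*% A - diag(ped$n))), 1e-8)
  }
  # deliberately inbred: full-sib line
  ped <- parse_pedigree(data.frame(
    id = c("f1", "f2", "a1", "a2", "b1", "b2", "c1"),
    sire = c("0", "0", "f1", "f1", "a1", "a1", "b1"),
    dam = c("0", "0", "f2", "f2", "a2", "a2", "b2")))
  A <- relationship_matrix(ped)
  Ai <- as.matrix(a_inverse(ped))
  expect_lt(max(abs(Ai %*% A - diag(ped$n))), 1e-8)
})

test_that("adding an unrelated founder leaves F and A entries unchanged", {
  set.seed(19)
  ped <- random_pedigree(40, founder_frac = 0.3)
  tab <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$id[ped$sire]),
                    dam = ifelse(is.na(ped$dam), "0", ped$id[ped$dam]))
  ped2 <- parse_pedigree(rbind(tab, data.frame(id = "NEW", sire = "0", dam = "0")))
  expect_equal(inbreeding(ped2)[ped$id], inbreeding(ped))
  expect_equal(relationship_matrix(ped2)[ped$id, ped$id],
               relationship_matrix(ped))
})

test_that("a_inverse rejects a degenerate Mendelian-sampling variance", {
  ped <- parse_pedigree(data.frame(id = c("p", "q", "o"),
                                   sire = c("0", "0", "p"),
                                   dam = c("0", "0", "q")))
  F_bad <- c(p = 1, q = 1, o = 0)  # forces d = 0
  expect_error(a_inverse(ped, F = F_bad), "Mendelian")
})

test_that("pedigree round-trips through CSV and reports depth metadata", {
  set.seed(23)
  ped <- random_pedigree(30)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = ped$id,
                       sire = ifelse(is.na(ped$sire), "0", ped$id[ped$sire]),
                       dam = ifelse(is.na(ped$dam), "0", ped$id[ped$dam])),
            f, row.names = FALSE, quote = FALSE)
  ped2 <- read_pedigree(f)
  expect_equal(ped2$id, ped$id)
  expect_equal(inbreeding(ped2), inbreeding(ped))
  ge <- generation_equivalents(ped)
  expect_true(all(ge >= 0))
  founders <- is.na(ped$sire) & is.na(ped$dam)
  expect_true(all(ge[founders] == 0))
  expect_true(all(ge[!founders] > 0))
  unlink(f)

  F <- inbreeding(ped)
  f2 <- tempfile(fileext = ".csv")
  write_inbreeding(F, f2)
  back <- read.csv(f2)
  expect_equal(back$F, unname(F))
  unlink(f2)
})
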