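make_table <- function(values, res_name = "ASP") {
  tibble::tibble(chain = "A", res_seq = 1L, res_name = res_name,
                 p1 = values[1], p2 = values[2], p3 = values[3])
}

# independent oracle: enumerate every predictor subset of size >= 2, keep those
# pairwise within tol, pick by (size, spread, lexicographic first member)
consensus_oracle <- function(v, tol) {
  preds <- names(v)
  best <- NULL
  for (size in length(v):2) {
    for (ix in utils::combn(length(v), size, simplify = FALSE)) {
      vv <- v[ix]
      if (max(vv) - min(vv) > tol) next
      cand <- list(size = size, spread = max(vv) - min(vv),
                   members = sort(preds[ix]), value = mean(vv))
      if (is.null(best) || cand$size > best$size ||
          (cand$size == best$size && cand$spread < best$spread) ||
          (cand$size == best$size && cand$spread == best$spread &&
           cand$members[1] < best$members[1])) best <- cand
    }
  }
  best
}

test_that("consensus pKa follows the two-of-three agreement rule", {
  r <- consensus_pka(make_table(c(4, 4, 4)), 0.5)
  expect_equal(r$pka, 4)
  expect_equal(r$supporting, "p1,p2,p3")

  r <- consensus_pka(make_table(c(4.0, 4.3, 7.9)), 0.5)
  expect_equal(r$pka, 4.15)
  expect_equal(r$supporting, "p1,p2")

  r <- consensus_pka(make_table(c(3, 5, 7)), 0.5)
  expect_false(r$resolved)
  expect_true(is.na(r$pka))
})

test_that("consensus agrees with a brute-force subset oracle", {
  set.seed(11)
  for (i in 1:50) {
    v <- round(runif(3, 2, 10), 2)
    names(v) <- c("p1", "p2", "p3")
    got <- consensus_pka(make_table(v), 0.5)
    want <- consensus_oracle(v, 0.5)
    if (is.null(want)) {
      expect_false(got$resolved)
    } else {
      expect_equal(got$pka, want$value, tolerance = 1e-12)
      expect_equal(got$supporting, paste(want$members, collapse = ","))
    }
  }
})

test_that("consensus is invariant under predictor column order", {
  tab <- make_table(c(4.1, 7.9, 4.4))
  perm <- tab[, c("chain", "res_seq", "res_name", "p3", "p1", "p2")]
  expect_equal(consensus_pka(tab, 0.5)$pka, consensus_pka(perm, 0.5)$pka)
})

test_that("entries with fewer than two predictors are rejected", {
  tab <- make_table(c(4, NA, NA))
  expect_error(consensus_pka(tab, 0.5), "< 2 predictor")
})

test_that("protonation rules match Henderson-Hasselbalch majority species", {
  cons <- function(rn, pka) tibble::tibble(chain = "A", res_seq = 1L,
                                           res_name = rn, pka = pka,
                                           resolved = TRUE, supporting = "p1,p2")
  # Asp pKa 5 at pH 4.5: protonated, charge 0
  st <- assign_protonation(cons("ASP", 5), 4.5)
  expect_true(st$protonated)
  expect_equal(st$side_chain_charge, 0L)
  # Lys far above pH: +1
  expect_equal(assign_protonation(cons("LYS", 10.4), 7)$side_chain_charge, 1L)
  # His 6.0: neutral at 7, +1 at 4.5
  expect_equal(assign_protonation(cons("HIS", 6), 7)$side_chain_charge, 0L)
  expect_equal(assign_protonation(cons("HIS", 6), 4.5)$side_chain_charge, 1L)

  # away from the margin, protonated iff the protonated fraction
  # 1/(1+10^(pH-pKa)) exceeds one half
  set.seed(5)
  for (i in 1:100) {
    pka <- runif(1, 2, 12)
    ph <- runif(1, 2, 12)
    if (abs(pka - ph) < 0.2) next  # margin region excluded by design
    frac <- 1 / (1 + 10^(ph - pka))
    for (rn in c("ASP", "GLU", "HIS", "LYS", "ARG", "TYR", "CYS")) {
      expect_equal(assign_protonation(cons(rn, pka), ph)$protonated,
                   frac > 0.5, info = sprintf("%s pKa %.2f pH %.2f", rn, pka, ph))
    }
  }
})

test_that("unresolved entries block protonation with a residue listing", {
  bad <- tibble::tibble(chain = "A", res_seq = 12L, res_name = "GLU",
                        pka = NA_real_, resolved = FALSE, supporting = "")
  expect_error(assign_protonation(bad, 7), "A12\\(GLU\\)")
})

test_that("net charge sums side-chain charges and is empty-safe", {
  empty <- assign_protonation(
    tibble::tibble(chain = character(), res_seq = integer(),
                   res_name = character(), pka = numeric(),
                   resolved = logical(), supporting = character()), 7)
  expect_equal(net_charge(empty), 0L)
})

test_that("net charge is monotonically non-decreasing as pH decreases", {
  set.seed(21)
  types <- c("ASP", "GLU", "HIS", "LYS", "ARG", "TYR", "CYS")
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    cons <- tibble::tibble(chain = "A", res_seq = seq_len(n),
                           res_name = sample(types, n, replace = TRUE),
                           pka = runif(n, 2, 12), resolved = TRUE,
                           supporting = "p1,p2")
    phs <- seq(9, 3, by = -0.5)
    qs <- vapply(phs, function(ph) net_charge(assign_protonation(cons, ph)),
                 integer(1))
    expect_true(all(diff(qs) >= 0))
  }
})

test_that("per-atom charge placement conserves the net charge exactly", {
  for (preset in c("CD1d_a1a2", "GM2AP", "SapA_dimer", "PruP3")) {
    sc <- make_pka_scenario(preset)
    cons <- consensus_pka(sc$pka_table)
    for (ph in c(7, 4.5)) {
      st <- assign_protonation(cons, ph)
      asg <- assign_charges_radii(sc$structure, st)
      expect_equal(sum(asg$charge), net_charge(st), tolerance = 1e-9)
      expect_true(all(asg$radius > 0))
    }
  }
})

test_that("charge placement targets the representative side-chain atoms", {
  sc <- make_pka_scenario("PruP3")
  st <- assign_protonation(consensus_pka(sc$pka_table), 7)
  asg <- assign_charges_radii(sc$structure, st)
  charged <- asg[abs(asg$charge) > 0, ]
  expect_true(all(charged$name %in% c("CG", "CD", "NE2", "NZ", "CZ", "OH", "SG")))

  gly <- atoms_from_xyz(matrix(rnorm(15), ncol = 3))
  st0 <- assign_protonation(
    tibble::tibble(chain = character(), res_seq = integer(),
                   res_name = character(), pka = numeric(),
                   resolved = logical(), supporting = character()), 7)
  asg0 <- assign_charges_radii(gly, st0)
  expect_true(all(asg0$charge == 0))

  odd <- gly
  odd$res_name <- "XYZ"
  expect_error(assign_charges_radii(odd, st0), "unknown residue")
})

test_that("pKa tables read from delimited text", {
  txt <- c("chain res_seq res_name propka hpp rosetta",
           "A 10 ASP 3.9 4.1 4.0",
           "A 20 HIS 6.2 6.0 6.1")
  tab <- read_pka_table(txt)
  expect_equal(nrow(tab), 2)
  got <- consensus_pka(tab, 0.5)
  expect_equal(got$pka, c(4.0, 6.1))
  expect_error(read_pka_table(c("chain res_seq res_name p1 p2",
                                "A 1 XXX 4 4")), "non-ionizable")
})
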