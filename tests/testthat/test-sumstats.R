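test_that("read_sumstats parses delimited tables, normalizes alleles, rejects bad rows", {
  path <- write_sumstats_text(c(
    "SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\ta\tg\t0.2\t0.10\t0.02\t1e-9\t5000",
    "rs2\tC\tT\t0.4\t-0.08\t0.02\t4e-8\t5000",
    "rs3\tA\tG\t0.3\t0.05\t0\t0.5\t5000",
    "rs4\tA\tG\t0.3\tnot_a_number\t0.02\t0.5\t5000",
    "rs5\tT\tC\t0.1\t0.07\t0.015\t2e-10\t5000"))
  suppressMessages(ss <- read_sumstats(path))
  expect_equal(ss$variant_id, c("rs1", "rs2", "rs5"))
  expect_equal(ss$effect_allele[1], "A")  # lowercase input uppercased
  expect_equal(ss$other_allele[1], "G")
  expect_equal(attr(ss, "n_dropped"), 2)  # se = 0 and unparseable beta
  expect_equal(ss$beta, c(0.10, -0.08, 0.07))
})

test_that("read_sumstats auto-detects comma delimiting and honors a custom column map", {
  path <- write_sumstats_text(c(
    "rsid,EA,OA,BETA,SE,P",
    "rs1,A,G,0.2,0.05,1e-9",
    "rs2,T,C,-0.1,0.04,0.02"))
  map <- c(variant_id = "rsid", effect_allele = "EA", other_allele = "OA",
           beta = "BETA", se = "SE", pvalue = "P")
  suppressMessages(ss <- read_sumstats(path, map))
  expect_equal(nrow(ss), 2)
  expect_true(all(is.na(ss$eaf)))
  expect_error(read_sumstats(path, map[names(map) != "se"]), "se")
  expect_error(
    read_sumstats(path, replace(map, "se", "STDERR")), "STDERR")
})

test_that("summary statistics round-trip through write_sumstats", {
  ss <- simple_sumstats(c("rs1", "rs2"), beta = c(0.125, -0.5),
                        se = c(0.025, 0.0625), pvalue = c(1e-9, 0.25))
  path <- tempfile(fileext = ".tsv")
  write_sumstats(ss, path)
  suppressMessages(back <- read_sumstats(path))
  attr(back, "n_dropped") <- NULL
  expect_equal(back, ss, ignore_attr = TRUE)
})

test_that("select_instruments applies a strict threshold, preserves order, and is monotone", {
  ss <- simple_sumstats(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.1, 0.1),
                        se = c(0.01, 0.01, 0.01),
                        pvalue = c(1e-9, 4e-8, 6e-8))
  sel <- select_instruments(ss, 5e-8)
  expect_equal(sel$variant_id, c("rs1", "rs2"))
  # boundary: strict excludes p == threshold, non-strict includes it
  at_thr <- simple_sumstats("rs4", 0.1, 0.01, 5e-8)
  expect_error(select_instruments(at_thr, 5e-8), "no instruments")
  expect_equal(select_instruments(at_thr, 5e-8, strict = FALSE)$variant_id, "rs4")
  # monotone nesting over random thresholds
  set.seed(7)
  ss2 <- simple_sumstats(sprintf("rs%d", 1:40), beta = 0.1, se = 0.01,
                         pvalue = runif(40))
  thresholds <- sort(runif(5, 0.05, 0.95))
  for (i in seq_len(length(thresholds) - 1)) {
    a <- select_instruments(ss2, thresholds[i])$variant_id
    b <- select_instruments(ss2, thresholds[i + 1])$variant_id
    expect_true(all(a %in% b))
  }
  expect_error(select_instruments(ss, 0.5 * NA), "p_threshold")
  all_null <- simple_sumstats("rs1", 0.1, 0.01, 0.5)
  expect_error(select_instruments(all_null, 5e-8), "5e-08")
})

test_that("harmonize aligns effects across allele codings", {
  exposure <- simple_sumstats("rs1", 0.2, 0.05, 1e-9, ea = "A", oa = "G")
  # swapped labels: outcome beta negated, flipped flagged
  outcome <- simple_sumstats("rs1", 0.1, 0.04, 0.01, ea = "G", oa = "A")
  suppressMessages(h <- harmonize(exposure, outcome))
  expect_equal(h$pairs$y, -0.1)
  expect_true(h$pairs$flipped)
  # identical coding: copied unchanged
  outcome2 <- simple_sumstats("rs1", 0.1, 0.04, 0.01, ea = "A", oa = "G")
  suppressMessages(h2 <- harmonize(exposure, outcome2))
  expect_equal(h2$pairs$y, 0.1)
  expect_false(h2$pairs$flipped)
  # strand complement, same orientation (A/G vs T/C)
  outcome3 <- simple_sumstats("rs1", 0.1, 0.04, 0.01, ea = "T", oa = "C")
  suppressMessages(h3 <- harmonize(exposure, outcome3))
  expect_equal(h3$pairs$y, 0.1)
  expect_false(h3$pairs$flipped)
  # strand complement, swapped orientation (A/G vs C/T)
  outcome4 <- simple_sumstats("rs1", 0.1, 0.04, 0.01, ea = "C", oa = "T")
  suppressMessages(h4 <- harmonize(exposure, outcome4))
  expect_equal(h4$pairs$y, -0.1)
  expect_true(h4$pairs$flipped)
})

test_that("harmonize drops palindromic variants with ambiguous frequencies", {
  # eaf 0.49 falls inside [0.42, 0.58]: ambiguous
  exposure <- simple_sumstats("rs1", 0.2, 0.05, 1e-9, ea = "A", oa = "T",
                              eaf = 0.49)
  outcome <- simple_sumstats("rs1", 0.1, 0.04, 0.01, ea = "A", oa = "T",
                             eaf = 0.49)
  suppressMessages(expect_error(harmonize(exposure, outcome),
                                "no overlapping instruments"))
  # same variant plus a clean one: dropped with reason, clean retained
  exposure2 <- rbind(exposure,
                     simple_sumstats("rs2", 0.3, 0.05, 1e-10, ea = "A",
                                     oa = "G"))
  outcome2 <- rbind(outcome,
                    simple_sumstats("rs2", 0.15, 0.04, 0.01, ea = "A",
                                    oa = "G"))
  suppressMessages(h <- harmonize(exposure2, outcome2))
  expect_equal(h$pairs$variant_id, "rs2")
  expect_equal(h$dropped$dropped_reason, "palindromic_ambiguous")
  # unambiguous palindrome (both eaf 0.2, same side): retained as-is
  exposure3 <- simple_sumstats("rs1", 0.2, 0.05, 1e-9, ea = "C", oa = "G",
                               eaf = 0.2)
  outcome3 <- simple_sumstats("rs1", 0.1, 0.04, 0.01, ea = "C", oa = "G",
                              eaf = 0.25)
  suppressMessages(h3 <- harmonize(exposure3, outcome3))
  expect_equal(h3$pairs$y, 0.1)
  # opposite-side frequencies are ambiguous under the same-side rule
  outcome4 <- simple_sumstats("rs1", 0.1, 0.04, 0.01, ea = "C", oa = "G",
                              eaf = 0.8)
  suppressMessages(expect_error(harmonize(exposure3, outcome4),
                                "no overlapping instruments"))
  # palindrome with missing eaf cannot be resolved
  outcome5 <- outcome3
  outcome5$eaf <- NA_real_
  suppressMessages(expect_error(harmonize(exposure3, outcome5),
                                "no overlapping instruments"))
})

test_that("harmonize records missing-in-outcome drops and rejects empty overlap", {
  exposure <- simple_sumstats(c("rs1", "rs2"), c(0.2, 0.3), c(0.05, 0.05),
                              c(1e-9, 1e-9))
  outcome <- simple_sumstats("rs1", 0.1, 0.04, 0.01)
  suppressMessages(h <- harmonize(exposure, outcome))
  expect_equal(h$dropped$variant_id, "rs2")
  expect_equal(h$dropped$dropped_reason, "missing_in_outcome")
  outcome_none <- simple_sumstats("rs9", 0.1, 0.04, 0.01)
  suppressMessages(expect_error(harmonize(exposure, outcome_none),
                                "no overlapping instruments"))
})

test_that("harmonization is idempotent and invariant to the outcome's sign convention", {
  set.seed(11)
  k <- 6
  exposure <- simple_sumstats(sprintf("rs%d", 1:k), beta = rnorm(k, 0.2, 0.05),
                              se = runif(k, 0.02, 0.06), pvalue = rep(1e-9, k),
                              ea = rep(c("A", "T", "G"), 2),
                              oa = rep(c("G", "C", "A"), 2),
                              eaf = runif(k, 0.1, 0.35))
  outcome <- exposure
  outcome$beta <- rnorm(k, 0, 0.05)
  outcome$se <- runif(k, 0.02, 0.06)
  # flip a subset of outcome records' allele labels and beta sign
  flip <- c(2, 5)
  tmp <- outcome$effect_allele[flip]
  outcome$effect_allele[flip] <- outcome$other_allele[flip]
  outcome$other_allele[flip] <- tmp
  outcome$beta[flip] <- -outcome$beta[flip]
  outcome$eaf[flip] <- 1 - outcome$eaf[flip]
  suppressMessages(h_ref <- harmonize(exposure, exposure))  # self-harmonization
  expect_equal(h_ref$pairs$y, exposure$beta)
  suppressMessages(h1 <- harmonize(exposure, outcome))
  # sign-convention invariance: un-flipped outcome gives identical pairs
  outcome0 <- outcome
  tmp <- outcome0$effect_allele[flip]
  outcome0$effect_allele[flip] <- outcome0$other_allele[flip]
  outcome0$other_allele[flip] <- tmp
  outcome0$beta[flip] <- -outcome0$beta[flip]
  outcome0$eaf[flip] <- 1 - outcome0$eaf[flip]
  suppressMessages(h0 <- harmonize(exposure, outcome0))
  expect_equal(h1$pairs[c("variant_id", "x", "sx", "y", "sy")],
               h0$pairs[c("variant_id", "x", "sx", "y", "sy")])
  # idempotence: rebuild the outcome from harmonized pairs and re-harmonize
  outcome_h <- exposure
  outcome_h$beta <- h1$pairs$y
  outcome_h$se <- h1$pairs$sy
  suppressMessages(h2 <- harmonize(exposure, outcome_h))
  expect_equal(h2$pairs$y, h1$pairs$y)
  expect_false(any(h2$pairs$flipped))
})

test_that("correlation matrices validate, reorder, and round-trip", {
  ids <- c("rs1", "rs2", "rs3")
  m <- matrix(c(1, 0.5, 0.2, 0.5, 1, -0.1, 0.2, -0.1, 1), 3, 3,
              dimnames = list(ids, ids))
  path <- tempfile(fileext = ".tsv")
  write_correlation_matrix(m, path)
  back <- read_correlation_matrix(path, ids)
  expect_identical(back, m)
  # permuted request order reorders rows and columns consistently
  perm <- read_correlation_matrix(path, rev(ids))
  expect_identical(perm, m[rev(ids), rev(ids)])
  expect_error(read_correlation_matrix(path, c(ids, "rs9")), "rs9")
  # 2x2 identity round trip
  i2 <- diag(2); dimnames(i2) <- list(c("a", "b"), c("a", "b"))
  path2 <- tempfile(fileext = ".tsv")
  write_correlation_matrix(i2, path2)
  expect_identical(read_correlation_matrix(path2, c("a", "b")), i2)
  # bad diagonal rejected
  m_bad <- m; m_bad[1, 1] <- 0.9
  path3 <- tempfile(fileext = ".tsv")
  write_correlation_matrix(m_bad, path3)
  expect_error(read_correlation_matrix(path3, ids), "diagonal")
  # asymmetry beyond tolerance rejected
  m_asym <- m; m_asym[1, 2] <- 0.6
  path4 <- tempfile(fileext = ".tsv")
  write_correlation_matrix(m_asym, path4)
  expect_error(read_correlation_matrix(path4, ids), "asymmetry")
})

test_that("SD units convert to pg/ml at 625 pg/ml per SD", {
  expect_equal(sd_to_pgml(1), 625.0)
  expect_equal(sd_to_pgml(0), 0)
  expect_equal(sd_to_pgml(2), 1250.0)
  expect_equal(sd_to_pgml(-0.4), -250.0)
})
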