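toy_table <- c(TRP = 17, PRO = 1, ASN = 2, HIS = 5, PHE = 12,
               MET = 13, TYR = 10, LEU = 4)

test_that("NPF divides the slope by the type reactivity", {
  slopes <- data.frame(chain = "A", resseq = 1:2, resname = c("TRP", "PRO"),
                       slope = c(0.017, 0.004))
  out <- npf(slopes, toy_table)
  expect_equal(out$npf, c(0.001, 0.004))  # PRO anchors the scale: npf == slope
  zero <- npf(data.frame(resname = "TRP", slope = 0), toy_table)
  expect_equal(zero$npf, 0)
  expect_error(npf(data.frame(resname = "XXX", slope = 1), toy_table), "missing")
})

test_that("NPF is homogeneous: degree 1 in slope, degree -1 in k/k_p", {
  slopes <- data.frame(resname = c("TRP", "HIS", "ASN"),
                       slope = c(0.02, 0.008, 0.001))
  base <- npf(slopes, toy_table)$npf
  expect_equal(npf(transform(slopes, slope = slope * 5), toy_table)$npf, 5 * base)
  expect_equal(npf(slopes, toy_table * 2)$npf, base / 2)
})

test_that("reactivity classes follow the printed thresholds", {
  expect_equal(as.character(classify_reactivity("TRP", c(TRP = 12))), "high")
  expect_equal(as.character(classify_reactivity("HIS", c(HIS = 5))), "moderate")
  expect_equal(as.character(classify_reactivity("ASN", c(ASN = 2))), "poor")
  # boundary convention: strict inequalities, boundaries fall downward
  expect_equal(as.character(classify_reactivity("TYR", c(TYR = 10))), "moderate")
  expect_equal(as.character(classify_reactivity("LEU", c(LEU = 4))), "poor")
})

test_that("shipped reactivity table is anchored on proline", {
  tab <- reactivity_table()
  expect_equal(unname(tab["PRO"]), 1)
  expect_true(all(tab > 0))
  expect_length(tab, 20L)
  # sulfur residues and aromatics sit in the high class
  expect_true(all(classify_reactivity(c("CYS", "MET", "TRP", "TYR"), tab) == "high"))
})

test_that("exclusion rules drop sulfur residues and poor reactives with a log", {
  d <- data.frame(chain = "A", resseq = c(80, 10, 20, 30),
                  resname = c("MET", "TRP", "ASN", "HIS"))
  out <- exclude_residues(d, table = toy_table)
  expect_false("MET" %in% out$resname)
  expect_match(paste(attr(out, "exclusion_log"), collapse = ";"), "MET80")

  out2 <- exclude_residues(d, min_kkp = 4, table = toy_table)
  expect_setequal(out2$resname, c("TRP", "HIS"))  # ASN (k/k_p = 2) excluded

  ident <- exclude_residues(d, exclude_sulfur = FALSE, exclude_gly = FALSE)
  expect_equal(nrow(ident), nrow(d))
  expect_length(attr(ident, "exclusion_log"), 0L)
})

test_that("filtering and normalizing commute", {
  slopes <- data.frame(chain = "A", resseq = 1:4,
                       resname = c("MET", "TRP", "ASN", "HIS"),
                       slope = c(0.05, 0.02, 0.001, 0.008))
  a <- npf(exclude_residues(slopes, table = toy_table), toy_table)
  b <- exclude_residues(npf(slopes, toy_table), table = toy_table)
  expect_equal(a$npf, b$npf)
  expect_equal(a$resname, b$resname)
})

test_that("native:denatured ratios behave as documented", {
  mk_slopes <- function(slope) {
    data.frame(chain = "A", resseq = 1:3, resname = c("TRP", "HIS", "ASN"),
               slope = slope, slope_se = 0.001)
  }
  sasa <- data.frame(chain = "A", resseq = 1:3,
                     resname = c("TRP", "HIS", "ASN"),
                     mean_sasa = c(220, 50, 10))
  ref <- c(TRP = 220, HIS = 150, ASN = 113)
  rat <- native_denatured_ratio(mk_slopes(c(0.002, 0.01, 0.004)),
                                mk_slopes(c(0.008, 0.01, 0.004)),
                                sasa, ref)
  expect_equal(rat$slope_ratio, c(0.25, 1, 1))    # 0.002/0.008 and equal slopes
  expect_equal(rat$sasa_ratio[1], 1)              # fully exposed: SASA_N == GXG
  # nonpositive denatured slope flagged unusable
  bad <- native_denatured_ratio(mk_slopes(c(0.002, 0.01, 0.004)),
                                mk_slopes(c(0.008, 0, 0.004)),
                                sasa, ref)
  expect_equal(nrow(bad), 2L)
  expect_match(paste(attr(bad, "unusable"), collapse = ";"), "HIS")
})

test_that("type-specific reactivity factors cancel in the slope ratio", {
  # the sequence-context cancellation argument: any multiplicative
  # factor common to the native and denatured slope of a residue
  # leaves Slope_N / Slope_D unchanged
  n <- data.frame(chain = "A", resseq = 1:3, resname = c("TRP", "HIS", "ASN"),
                  slope = c(0.02, 0.005, 0.0008))
  d <- data.frame(chain = "A", resseq = 1:3, resname = c("TRP", "HIS", "ASN"),
                  slope = c(0.08, 0.01, 0.004))
  sasa <- data.frame(chain = "A", resseq = 1:3,
                     resname = c("TRP", "HIS", "ASN"),
                     mean_sasa = c(55, 75, 28))
  ref <- c(TRP = 220, HIS = 150, ASN = 113)
  base <- native_denatured_ratio(n, d, sasa, ref)
  ctx <- c(3.7, 0.4, 1.9)
  scaled <- native_denatured_ratio(transform(n, slope = slope * ctx),
                                   transform(d, slope = slope * ctx),
                                   sasa, ref)
  expect_equal(scaled$slope_ratio, base$slope_ratio, tolerance = 1e-12)
})

test_that("a user-supplied denatured ensemble can replace the GXG model", {
  n <- data.frame(chain = "A", resseq = 1, resname = "TRP", slope = 0.02)
  d <- data.frame(chain = "A", resseq = 1, resname = "TRP", slope = 0.04)
  sasa_n <- data.frame(chain = "A", resseq = 1, resname = "TRP", mean_sasa = 100)
  sasa_d <- data.frame(chain = "A", resseq = 1, resname = "TRP", mean_sasa = 200)
  rat <- native_denatured_ratio(n, d, sasa_n, sasa_denatured = sasa_d)
  expect_equal(rat$sasa_ratio, 0.5)
})
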