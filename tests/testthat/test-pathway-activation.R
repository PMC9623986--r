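test_that("the reference profile is the per-gene geometric mean of controls", {
  c1 <- make_profile("n1", g = 10, h = 100)
  c2 <- make_profile("n2", g = 1000, h = 100)
  ref <- build_reference(list(c1, c2), offset = 0)
  expect_equal(unname(ref$values["g"]), sqrt(10 * 1000))  # 100
  expect_equal(unname(ref$values["h"]), 100)
  # a single control is its own geometric mean (plus offset)
  ref1 <- build_reference(list(c1), offset = 1)
  expect_equal(ref1$values, c1$values + 1)
  # identical controls: idempotent
  ref2 <- build_reference(list(c1, c1, c1), offset = 0)
  expect_equal(ref2$values, c1$values)
  expect_error(build_reference(list()), "at least one control")
})

test_that("case-to-normal ratios apply the offset symmetrically", {
  ctrl <- make_profile("n", g = 99, z = 0)
  ref <- build_reference(list(ctrl), offset = 1)
  tum <- make_profile("t", g = 199, z = 0)
  cnr <- compute_cnr(tum, ref)
  expect_equal(unname(cnr$cnr["g"]), 200 / 100)
  # zero counts on both sides floor at ratio exactly 1
  expect_equal(unname(cnr$cnr["z"]), 1)
  # a tumor identical to the single control has all ratios 1
  self <- compute_cnr(ctrl, ref)
  expect_equal(unname(self$cnr), rep(1, 2))
  disjoint <- make_profile("t2", other = 5)
  expect_error(compute_cnr(disjoint, ref), "no gene overlap")
})

test_that("PAL reproduces the analytic worked examples exactly", {
  cnr <- structure(list(sample_id = "t",
                        cnr = c(a = 1, b = 1, c = 1), n_dropped = 0L),
                   class = "CnrVector")
  pw <- pathway("p", c(a = 1, b = -1, c = 0.5))
  expect_identical(as.numeric(compute_pal(cnr, pw)), 0)

  cnr$cnr <- c(a = 10)
  expect_equal(as.numeric(compute_pal(cnr, pathway("p1", c(a = 1)))), 1)

  cnr$cnr <- c(a = 100, b = 10, c = 1)
  expect_equal(as.numeric(compute_pal(cnr, pw)), (2 - 1 + 0) / 2.5)  # 0.4

  # an ARR = 0 member never moves the score
  cnr$cnr <- c(a = 100, b = 10, c = 1, d = 123456)
  pw0 <- pathway("p0", c(a = 1, b = -1, c = 0.5, d = 0))
  expect_equal(as.numeric(compute_pal(cnr, pw0)), 0.4)
})

test_that("PAL matches brute-force evaluation on 1000 random small pathways", {
  set.seed(101)
  genes <- sprintf("g%02d", 1:12)
  for (i in 1:1000) {
    measured <- sample(genes, sample(5:12, 1))
    cnr <- structure(list(sample_id = "t",
                          cnr = stats::setNames(10^runif(length(measured), -2, 2),
                                                measured),
                          n_dropped = 0L), class = "CnrVector")
    pw <- random_pathway(paste0("p", i), genes, sample(2:10, 1))
    expected <- oracle_pal(cnr$cnr, pw$members)
    got <- suppressWarnings(compute_pal(cnr, pw))
    if (is.na(expected)) {
      expect_true(attr(got, "undefined"))
      expect_identical(as.numeric(got), 0)
    } else {
      expect_equal(as.numeric(got), expected, tolerance = 1e-12)
    }
  }
})

test_that("PAL is linear in log10 ratio and bounded by the largest member", {
  set.seed(11)
  genes <- sprintf("g%d", 1:8)
  cnr_vals <- stats::setNames(10^runif(8, -1, 1), genes)
  cnr <- structure(list(sample_id = "t", cnr = cnr_vals, n_dropped = 0L),
                   class = "CnrVector")
  activ <- pathway("act", stats::setNames(rep(1, 8), genes))
  for (c_shift in c(-2, 0.5, 3)) {
    shifted <- cnr
    shifted$cnr <- cnr_vals * 10^c_shift
    expect_equal(as.numeric(compute_pal(shifted, activ)),
                 as.numeric(compute_pal(cnr, activ)) + c_shift,
                 tolerance = 1e-12)
  }
  for (i in 1:50) {
    pw <- random_pathway(paste0("b", i), genes, sample(2:8, 1))
    got <- suppressWarnings(compute_pal(cnr, pw))
    contributing <- names(pw$members)[pw$members != 0]
    if (!attr(got, "undefined"))
      expect_lte(abs(as.numeric(got)),
                 max(abs(log10(cnr_vals[contributing]))) + 1e-12)
  }
})

test_that("an unmeasured or all-neutral pathway yields a flagged zero", {
  cnr <- structure(list(sample_id = "t", cnr = c(a = 2), n_dropped = 0L),
                   class = "CnrVector")
  pw <- pathway("p", c(zz = 1, yy = -1))
  expect_warning(v <- compute_pal(cnr, pw), "undefined")
  expect_identical(as.numeric(v), 0)
  expect_true(attr(v, "undefined"))
  neutral <- pathway("p2", c(a = 0, b = 0))
  expect_warning(v2 <- compute_pal(cnr, neutral), "undefined")
  expect_true(attr(v2, "undefined"))
})

test_that("the PAL matrix is zero for self-comparison and order-equivariant", {
  ctrl <- make_profile("n", a = 10, b = 20, c = 30, role = "normal")
  ref <- build_reference(list(ctrl))
  pws <- list(pathway("p1", c(a = 1, b = -1)), pathway("p2", c(b = 1, c = 0.5)))
  m <- pal_matrix(list(ctrl), ref, pws)
  expect_equal(as.numeric(m), c(0, 0))
  # replicate profiles give identical rows
  rep1 <- make_profile("r1", a = 55, b = 5, c = 70, role = "tumor")
  rep2 <- make_profile("r2", a = 55, b = 5, c = 70, role = "tumor")
  m2 <- pal_matrix(list(rep1, rep2), ref, pws)
  expect_equal(unname(m2[1, ]), unname(m2[2, ]))
  # permuting the pathway list permutes columns identically
  m3 <- pal_matrix(list(rep1, rep2), ref, rev(pws))
  expect_equal(m3[, c("p1", "p2")], m2[, c("p1", "p2")])
})

test_that("group PAL differences are signed means with label antisymmetry", {
  pal <- matrix(c(2, 4, 1, 1), ncol = 1,
                dimnames = list(c("s1", "s2", "s3", "s4"), "p"))
  groups <- c(s1 = "poor", s2 = "poor", s3 = "favorable", s4 = "favorable")
  d <- pal_group_difference(pal, groups)
  expect_equal(d$difference, 2)
  swapped <- ifelse(groups == "poor", "favorable", "poor")
  names(swapped) <- names(groups)
  expect_equal(pal_group_difference(pal, swapped)$difference, -2)
  # identical groups: all differences zero
  pal2 <- matrix(c(1, 1, 1, 1), ncol = 1,
                 dimnames = list(names(groups), "p"))
  expect_equal(pal_group_difference(pal2, groups)$difference, 0)
  all_poor <- stats::setNames(rep("poor", 4), names(groups))
  expect_error(pal_group_difference(pal, all_poor), "non-empty")
})
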