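uniform20 <- rep(1 / 20, 20)

test_that("background-equal models yield an all-zero track of the right length", {
  bg <- typical_background()
  m <- nologo_model(bg, bg, matrix(1 / 3, 3, 3), bg)
  set.seed(1)
  seqc <- random_window(60)
  tr <- scan_protein(seqc, m)
  expect_equal(nrow(tr), 60 - 13 + 1)
  expect_equal(tr$llr, rep(0, nrow(tr)), tolerance = 1e-12)
  expect_warning(empty <- scan_protein("LEEEL", m), "shorter")
  expect_equal(nrow(empty), 0L)
})

test_that("the track argmax localizes high-scoring planted motifs", {
  m <- synthetic_nes_model()
  set.seed(1)
  hits <- 0L
  for (i in 1:200) {
    sq <- plant_high_scoring(m, len = 100L, pos = 40L, min_llr = 7)
    tr <- scan_protein(sq, m)
    hits <- hits + (abs(tr$start[which.max(tr$llr)] - 40L) <= 2L)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("best_start takes the llr argmax with ties to the smallest index", {
  m <- synthetic_nes_model()
  # homogeneous repeat window: all starts tie, so the first wins
  expect_equal(best_start(strrep("A", 25), m), 1L)
  set.seed(6)
  for (i in 1:10) {
    w <- random_window(25)
    tr <- scan_protein(w, m)
    expect_equal(best_start(w, m), tr$start[which.max(tr$llr[1:12])])
  }
})

test_that("configuration posterior is a normalized Bayes update", {
  set.seed(10)
  for (seed in 1:100) {
    m <- random_model(seed)
    w <- random_window(13)
    post <- posterior_configurations(w, m)
    expect_equal(sum(post), 1, tolerance = 1e-9)
    expect_equal(unname(post), bf_config_posterior(w, m), tolerance = 1e-12)
  }
  m1 <- nologo_model(uniform20, uniform20, matrix(1 / 3, 3, 3), uniform20,
                     configs = spacer_config(3, 2, 1))
  expect_equal(unname(posterior_configurations(random_window(13), m1)), 1)
})

test_that("start posterior normalizes marginal likelihoods across candidate starts", {
  set.seed(20)
  for (seed in 1:30) {
    m <- random_model(seed)
    w <- random_window(25)
    ps <- posterior_start(w, m)
    expect_length(ps, 12L)
    expect_equal(sum(ps), 1, tolerance = 1e-9)
    expect_equal(ps, bf_start_posterior(w, m, 12L), tolerance = 1e-10)
  }
  m <- random_model(3)
  expect_equal(posterior_start(strrep("L", 25), m), rep(1 / 12, 12),
               tolerance = 1e-12)
})

test_that("start range is clamped with a warning on short windows", {
  m <- synthetic_nes_model()
  expect_warning(ps <- posterior_start(random_window(20), m), "start positions")
  expect_length(ps, 20 - 13 + 1)
  expect_equal(sum(ps), 1, tolerance = 1e-9)
})

test_that("hydrophobic posterior sums to 4 and matches the double-sum oracle", {
  set.seed(30)
  for (seed in 1:30) {
    m <- random_model(seed)
    w <- random_window(25)
    hp <- suppressWarnings(posterior_hydrophobic(w, m))
    expect_equal(sum(hp), 4, tolerance = 1e-9)
    expect_true(all(hp >= -1e-12 & hp <= 1 + 1e-12))
    expect_equal(hp, bf_hydrophobic_posterior(w, m, 12L), tolerance = 1e-10)
  }
})

test_that("degenerate one-config one-start decoding returns the anchor indicator", {
  m1 <- nologo_model(uniform20, uniform20, matrix(1 / 3, 3, 3), uniform20,
                     configs = spacer_config(3, 2, 1))
  w <- random_window(10)
  hp <- posterior_hydrophobic(w, m1, scan_settings(max_start_positions = 1))
  ind <- numeric(10)
  ind[hydrophobic_offsets(spacer_config(3, 2, 1)) + 1] <- 1
  expect_equal(hp, ind)
})

test_that("best-start view places all start mass on the llr argmax", {
  m <- synthetic_nes_model()
  set.seed(40)
  w <- plant_high_scoring(m, len = 25L, pos = 5L)
  bs <- best_start(w, m)
  hp <- posterior_hydrophobic(w, m, marginalize_start = FALSE)
  pc <- posterior_configurations(w, m, start = bs)
  lay_sum <- sum(hp[bs + 0:(m$total_length - 1)])
  expect_equal(lay_sum, 4, tolerance = 1e-9)
  expect_equal(sum(hp), 4, tolerance = 1e-9)
  expect_equal(sum(pc), 1, tolerance = 1e-9)
})

test_that("single-configuration scores rank windows identically under any parent set", {
  # the single-config model's prior is a scalar, so renormalizing it from
  # different allowed supersets shifts all llrs by a constant
  sl <- rbind(c(.2, .3, .5), c(.1, .8, .1), c(.6, .2, .2))
  mA <- nologo_model(rep(1 / 20, 20), rep(1 / 20, 20), sl, rep(1 / 20, 20),
                     configs = c("3-2-1", "2-2-1", "1-1-1"))
  mB <- nologo_model(rep(1 / 20, 20), rep(1 / 20, 20), sl, rep(1 / 20, 20),
                     configs = c("3-2-1", "3-3-3"))
  m321A <- nologo_model(mA$phi, mA$spacer, sl, mA$background, configs = "3-2-1")
  set.seed(50)
  w1 <- random_window(13); w2 <- random_window(13)
  d <- llr(w1, m321A) - llr(w2, m321A)
  expect_equal(sign(d), sign(likelihood(w1, m321A, log = TRUE) -
                             likelihood(w2, m321A, log = TRUE)))
})

test_that("raising the anchor leucine probability raises an all-leucine-anchor llr", {
  spa <- stats::setNames(rep(0.05, 20), AA_ALPHABET)
  w <- "LEEELEELELAAA"   # 3-2-1 layout with L at every anchor
  lls <- vapply(c(0.3, 0.5, 0.7), function(pL) {
    phi <- stats::setNames(rep((1 - pL) / 19, 20), AA_ALPHABET); phi["L"] <- pL
    m <- nologo_model(phi, spa, matrix(1 / 3, 3, 3), rep(1 / 20, 20),
                      configs = spacer_config(3, 2, 1))
    llr(w, m)
  }, numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("profile alignment anchors the best start at the requested column", {
  mk <- function(vec, bs) list(hydrophobic_posterior = vec, best_start = bs)
  v <- seq(0.01, 0.2, length.out = 20)
  out <- align_profiles_for_heatmap(list(mk(v, 6L)), anchor = 6L, width = 25L)
  expect_equal(out[1, 1:20], v, ignore_attr = TRUE)
  # best start 8: shifted left by 2, vacated right columns are NA
  v25 <- seq_len(25) / 100
  out2 <- align_profiles_for_heatmap(list(mk(v25, 8L)), anchor = 6L, width = 25L)
  expect_equal(out2[1, 1:23], v25[3:25], ignore_attr = TRUE)
  expect_true(all(is.na(out2[1, 24:25])))
  # round trip: re-anchoring the shifted row at the original column recovers it
  out3 <- align_profiles_for_heatmap(list(mk(v, 4L)), anchor = 6L, width = 25L)
  expect_equal(out3[1, 3:22], v, ignore_attr = TRUE)   # shifted right by 2
  back <- align_profiles_for_heatmap(list(mk(out3[1, ], 6L)), anchor = 4L,
                                     width = 25L)
  expect_equal(back[1, 1:20], v, ignore_attr = TRUE)
  # a short window that cannot be shifted fully is edge-anchored: the
  # desired shift of 4 would push a 22-residue profile past column 25
  v22 <- seq_len(22) / 100
  out4 <- align_profiles_for_heatmap(list(mk(v22, 2L)), anchor = 6L, width = 25L)
  expect_equal(out4[1, 4:25], v22, ignore_attr = TRUE)
  expect_true(all(is.na(out4[1, 1:3])))
})
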