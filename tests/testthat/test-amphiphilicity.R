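test_that("windowed hydropathy of a homopolymer is the residue score everywhere", {
  kd <- hydropathy_scale("kd")
  prof <- windowed_hydropathy(strrep("L", 30), kd, window = 7)
  expect_equal(prof$mean_h, rep(unname(kd["L"]), 24))
  # window = sequence length collapses to the global mean
  s <- "AVGLKDE"
  p1 <- windowed_hydropathy(s, kd, window = 7)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$mean_h, mean(kd[strsplit(s, "")[[1]]]), ignore_attr = TRUE)
  # profile length and bounds
  p2 <- windowed_hydropathy(study_sequence("melittin"), kd, window = 9)
  expect_equal(nrow(p2), 26 - 9 + 1)
  expect_true(all(p2$mean_h >= min(kd) & p2$mean_h <= max(kd)))
  expect_error(windowed_hydropathy("AAABBB", kd, 3), "unknown")
})

test_that("hydrophobic moment equals a direct-summation oracle on random windows", {
  set.seed(42)
  eis <- hydropathy_scale("eisenberg")
  for (i in 1:100) {
    len <- sample(5:18, 1)
    win <- paste(sample(names(eis), len, replace = TRUE), collapse = "")
    h <- unname(eis[strsplit(win, "")[[1]]])
    delta <- 100 * pi / 180
    sx <- 0; cx <- 0
    for (n in seq_len(len)) {           # brute-force term-by-term sum
      sx <- sx + h[n] * sin(n * delta)
      cx <- cx + h[n] * cos(n * delta)
    }
    expect_equal(hydrophobic_moment(win, eis), sqrt(sx^2 + cx^2) / len,
                 tolerance = 1e-10)
  }
})

test_that("moment limit cases: zero scores, single residue", {
  zero <- hydropathy_scale("eisenberg")
  zero[] <- 0
  expect_equal(hydrophobic_moment("AVLKD", zero), 0)
  eis <- hydropathy_scale("eisenberg")
  expect_equal(hydrophobic_moment("K", eis), abs(unname(eis["K"])))
})

test_that("the moment is invariant to a common phase shift and linear in the scale", {
  eis <- hydropathy_scale("eisenberg")
  win <- "GIGAVLKVLTTGL"
  h <- unname(eis[strsplit(win, "")[[1]]])
  base <- hydrophobic_moment(win, eis)
  for (phi in c(0.3, 1.2, 2.9)) {       # rotation invariance of the vector sum
    ang <- seq_along(h) * 100 * pi / 180 + phi
    mu <- sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2) / length(h)
    expect_equal(mu, base, tolerance = 1e-12)
  }
  doubled <- eis * 2
  attr(doubled, "scale_name") <- "eisenberg"
  expect_equal(hydrophobic_moment(win, doubled), 2 * base, tolerance = 1e-12)
})

test_that("sliding moment profile agrees with per-window evaluation", {
  seq <- study_sequence("melittin")
  mp <- moment_profile(seq, window = 11)
  i <- 5                                 # window starting at residue 5
  win <- substr(seq, i, i + 10)
  expect_equal(mp$mu_h[i], hydrophobic_moment(win), tolerance = 1e-12)
})

test_that("segment detection finds exactly the supra-threshold block", {
  prof <- data.frame(position = 1:50,
                     mu_h = ifelse(1:50 >= 20 & 1:50 <= 30, 0.6, 0.05))
  expect_equal(detect_amphiphilic_segments(prof, 0.4),
               data.frame(start = 20L, end = 30L))
  prof$mu_h <- 0
  expect_equal(nrow(detect_amphiphilic_segments(prof, 0.4)), 0)
})

test_that("P56S MSP amphiphilic segments overlap the helix-2 and C-terminal regions", {
  mp <- moment_profile(study_sequence("msp_p56s"))
  segs <- detect_amphiphilic_segments(mp, mu_threshold = 0.35)
  hits <- function(a, b) any(segs$start <= b & segs$end >= a)
  expect_true(hits(22, 32))
  expect_true(hits(116, 125))
})

test_that("profile comparison: self-comparable, zero-vs-positive not comparable", {
  mp <- moment_profile(study_sequence("msp_p56s"))
  self <- compare_profiles(mp, mp, mu_threshold = 0.35)
  expect_true(self$comparable_profile)
  # the segment containing the global peak is always self-comparable
  peak_pos <- mp$position[which.max(mp$mu_h)]
  at_peak <- self$segments$start <= peak_pos & self$segments$end >= peak_pos
  expect_true(any(self$segments$comparable[at_peak]))
  flat <- mp
  flat$mu_h <- 0
  none <- compare_profiles(flat, mp, mu_threshold = 0.35, min_len = 1)
  expect_false(none$comparable_profile)
  expect_equal(nrow(none$segments), 0)
  expect_error(compare_profiles(mp, moment_profile(study_sequence("melittin"),
                                                   delta = 160)),
               "different")
})

test_that("MSP-vs-reference peptide moment comparison reproduces the frozen regression", {
  msp <- moment_profile(study_sequence("msp_p56s"))
  mel <- moment_profile(study_sequence("melittin"))
  asy <- moment_profile(study_sequence("asyn"))
  # global per-residue peaks of the three profiles (regression values)
  expect_equal(max(msp$mu_h), 0.5371565, tolerance = 1e-6)
  expect_equal(max(mel$mu_h), 0.5675710, tolerance = 1e-6)
  expect_equal(max(asy$mu_h), 0.5627009, tolerance = 1e-6)
  cmp <- compare_profiles(msp, mel, mu_threshold = 0.35)
  seg2 <- cmp$segments[cmp$segments$start <= 32 & cmp$segments$end >= 22, ]
  segC <- cmp$segments[cmp$segments$start <= 125 & cmp$segments$end >= 116, ]
  expect_equal(nrow(seg2), 1)
  expect_equal(nrow(segC), 1)
  # both segments reach > 70% of the melittin peak moment
  expect_gt(seg2$peak_mu_h / cmp$max_b, 0.70)
  expect_gt(segC$peak_mu_h / cmp$max_b, 0.80)
})

test_that("transmembrane screen: C-terminal anchor found, none inside the MSP domain", {
  fl <- tm_screen(study_sequence("vapb_p56s_synthetic_fl"))
  expect_gt(fl$peak_position, 125)
  expect_gte(nrow(fl$segments), 1)
  msp <- tm_screen(study_sequence("msp_p56s"))
  expect_equal(nrow(msp$segments), 0)
  expect_lt(max(msp$profile$mean_h), 1.0)
})
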