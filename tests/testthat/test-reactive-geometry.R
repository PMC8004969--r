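test_that("reactive distances reproduce hand-built and generated geometry", {
  traj <- tiny_reactive_traj(C = c(3.7, 0, 0), HS = c(2.61, 0, 0))
  rd <- compute_reactive_distances(traj)
  expect_equal(rd$d_C_OH, 3.7)
  expect_equal(rd$d_HproS_OH, 2.61)   # H on the C->OH segment, 1.09 from C

  g <- gen_reactive_frames(200, 4.2, 0.4, phi_deg = 25, seed = 5)
  rd2 <- compute_reactive_distances(g$trajectory)
  expect_equal(rd2$d_C_OH, g$ground_truth$d, tolerance = 1e-9)
  expect_equal(rd2$d_HproS_OH, g$ground_truth$d_H, tolerance = 1e-9)
  expect_equal(rd2$d_HproR_OH, g$ground_truth$d_H, tolerance = 1e-9)
  expect_equal(nrow(rd2), 200L)
  expect_equal(rd2$frame, g$trajectory$frame)
})

test_that("two-criterion classification follows the inclusive/strict boundary rules", {
  cases <- data.frame(
    d_H = c(2.5, 3.5, 2.9, 3.0, 3.7),
    d_C = c(3.7, 3.7, 2.5, 3.7, 3.7),
    wo  = c(TRUE, TRUE, FALSE, TRUE, FALSE),   # strict <
    pc  = c(TRUE, FALSE, FALSE, TRUE, FALSE))  # inclusive <= 3
  rd <- data.frame(d_C_OH = cases$d_C, d_HproS_OH = cases$d_H,
                   d_HproR_OH = cases$d_C + 1)  # proR never oriented
  cls <- classify_frames(rd, cutoff = 3)
  expect_equal(cls$wo_S, cases$wo)
  expect_equal(cls$pc_S, cases$pc)
  expect_false(any(cls$wo_R))
  expect_equal(cls$wo_any, cases$wo)
  expect_equal(cls$pc_any, cases$pc)
})

test_that("pre-catalytic implies well-oriented and classification matches a brute-force re-check", {
  g <- gen_reactive_frames(500, 3.6, 0.6, phi_deg = 40, seed = 9)
  cls <- classify_frames(compute_reactive_distances(g$trajectory))
  expect_true(all(!cls$pc_S | cls$wo_S))
  expect_true(all(!cls$pc_R | cls$wo_R))
  expect_equal(cls$wo_any, cls$wo_S | cls$wo_R)
  expect_equal(cls$pc_any, cls$pc_S | cls$pc_R)
  # independent per-frame re-evaluation of the two inequalities
  for (i in seq_len(nrow(cls))) {
    expect_identical(cls$wo_S[i], cls$d_HproS_OH[i] < cls$d_C_OH[i])
    expect_identical(cls$pc_S[i],
                     cls$d_HproS_OH[i] <= 3 && cls$d_HproS_OH[i] < cls$d_C_OH[i])
  }
})

test_that("percentages are monotone in the cutoff and meet the analytic fraction", {
  g <- gen_reactive_frames(10000, 3.5, 0.5, phi_deg = 0, seed = 42)
  rd <- compute_reactive_distances(g$trajectory)
  cuts <- c(1, 2, 2.5, 3, 4, 8, Inf)
  pcs <- vapply(cuts, function(ct)
    summarize_geometry(classify_frames(rd, cutoff = ct))$pct_precatalytic,
    numeric(1))
  expect_true(all(diff(pcs) >= 0))
  cls_inf <- classify_frames(rd, cutoff = Inf)
  s_inf <- summarize_geometry(cls_inf)
  expect_equal(s_inf$pct_precatalytic, s_inf$pct_well_oriented)

  # closed-form truncated-normal expectation, 99% binomial CI
  p0 <- g$expected$precatalytic
  expect_equal(p0, (pnorm((3 + 1.09 - 3.5) / 0.5) -
                      pnorm((1.09 - 3.5) / 0.5)) /
                 (1 - pnorm((1.09 - 3.5) / 0.5)), tolerance = 1e-12)
  phat <- summarize_geometry(classify_frames(rd))$pct_precatalytic / 100
  halfwidth <- qnorm(0.995) * sqrt(p0 * (1 - p0) / 10000)
  expect_lt(abs(phat - p0), halfwidth)
})

test_that("summaries average distances and count percentage flags", {
  rd <- data.frame(frame = 0:3, time_ns = (0:3) * 0.5,
                   d_C_OH = c(3, 4, 5, 6),
                   d_HproS_OH = c(2, 5, 2.5, 7),
                   d_HproR_OH = c(4, 5, 6, 7))
  cls <- classify_frames(rd)
  s <- summarize_geometry(cls)
  expect_equal(s$n_frames, 4L)
  expect_equal(s$mean_d_C_OH, 4.5)
  expect_equal(s$pct_precatalytic, 50)   # frames 1 and 3
  expect_equal(s$pct_well_oriented, 50)  # proR never closer than C

  # single repeated frame: means equal the frame's values
  one <- classify_frames(rd[rep(2, 5), ])
  s1 <- summarize_geometry(one)
  expect_equal(s1$mean_d_HproS_OH, 5)
  # discard window drops early frames
  s2 <- summarize_geometry(cls, discard_ns = 1)
  expect_equal(s2$n_frames, 2L)
  expect_error(summarize_geometry(cls, discard_ns = 100), "no frames")
})

test_that("summary comparison reports folds and distance shifts with display rounding", {
  geo <- alox15_geometry_table()
  row <- function(sys, sub) {
    r <- geo[geo$system == sys & geo$substrate == sub, ]
    geometry_summary(sys, r$mean_d_C_OH, r$mean_d_HproS_OH,
                     r$mean_d_HproR_OH, r$pct_well_oriented,
                     r$pct_precatalytic)
  }
  aa <- compare_summaries(row("Trp181Glu", "AA"), row("WT", "AA"))
  expect_equal(aa$fold_precatalytic, 55.69 / 3.40, tolerance = 1e-12)
  expect_equal(aa$display_fold_precatalytic, 16)
  expect_equal(aa$display_delta_mean_d_C_OH, 1.5)
  la <- compare_summaries(row("Trp181Glu", "LA"), row("WT", "LA"))
  expect_equal(la$display_fold_precatalytic, 1.6)
  expect_equal(la$display_delta_mean_d_C_OH, 0.3)

  zero <- row("WT", "AA"); zero$pct_precatalytic <- 0
  expect_error(compare_summaries(row("Trp181Glu", "AA"), zero), "undefined")
})
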