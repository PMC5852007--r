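test_that("identity registration yields zero displacement for confident pairs", {
  cfg <- mini_phantom_config()
  f0 <- render_tag_image(cfg, 0)
  cc <- htm_correspondences(f0, f0)
  expect_s3_class(cc, "htm_correspondences")
  expect_equal(nrow(cc), 64 / 16 * 64 / 16 * 64)   # 1024 windows for 64x64
  ok <- cc$flag == "ok"
  expect_gt(sum(ok), 40)
  expect_true(all(cc$ref_row[ok] == cc$mov_row[ok]))
  expect_true(all(cc$ref_col[ok] == cc$mov_col[ok]))
})

test_that("integer translation is recovered exactly at interior windows", {
  sh <- c(4, 6)
  cfg <- mini_phantom_config(motion = "translation", translation = sh,
                             frames = 2L)
  f0 <- render_tag_image(cfg, 0)
  f1 <- render_tag_image(cfg, 1)
  cc <- htm_correspondences(f0, f1)
  g <- part_grid(dim(f0))
  ti <- rep(seq_len(nrow(g$template_origins)), each = 64)
  to <- g$template_origins[ti, ]
  interior <- to[, 1] + sh[1] >= 0 & to[, 1] + 16 + sh[1] <= 64 &
              to[, 2] + sh[2] >= 0 & to[, 2] + 16 + sh[2] <= 64
  keep <- cc$flag != "degenerate" & interior
  expect_gt(sum(keep), 50)
  expect_true(all(cc$ref_row[keep] - cc$mov_row[keep] == sh[1]))
  expect_true(all(cc$ref_col[keep] - cc$mov_col[keep] == sh[2]))
})

test_that("template matching recovers shifts and falls back on flat patches", {
  cfg <- mini_phantom_config()
  f0 <- render_tag_image(cfg, 0)
  mt <- match_template(f0, f0, c(16, 16))
  expect_equal(mt$region$origin, c(16, 16))
  expect_equal(mt$peak_cc, 1, tolerance = 1e-12)
  # uniform image: everything degenerate, template keeps its own location
  flat <- matrix(0.3, 64, 64)
  mtf <- match_template(flat, flat, c(32, 16))
  expect_true(mtf$degenerate)
  expect_equal(mtf$region$origin, c(32, 16))
})

test_that("overlap refinement shrinks regions and tracks identity", {
  cfg <- mini_phantom_config()
  f0 <- render_tag_image(cfg, 0)
  # template over the annulus (centre 31.5: offset by ~outer radius)
  to <- c(10, 24)
  mt <- match_template(f0, f0, to)
  r <- refine_by_overlap(f0, f0, to, 16L, mt$region, c(14L, 12L, 10L))
  expect_equal(r$region$size, 10)
  expect_equal(r$region$origin, to + 3)
  # one 6 px step under an 8 x 8 segment
  r6 <- refine_by_overlap(f0, f0, to, 8L, list(origin = to, size = 8L), 6L)
  expect_equal(r6$region$size, 6)
  expect_error(refine_by_overlap(f0, f0, to, 16L, mt$region, c(10L, 12L)),
               "strictly decreasing")
})

test_that("children match at their relative offsets under identity", {
  cfg <- mini_phantom_config()
  f0 <- render_tag_image(cfg, 0)
  to <- c(10, 24)
  seg_origins <- to[c(1, 1, 1, 1, 2, 2, 2, 2)]
  dim(seg_origins) <- c(4, 2)
  seg_origins <- seg_origins + htmotion:::child_offsets(16L)
  rs <- match_children(f0, f0, seg_origins, 8L, to, 16L,
                       list(origin = to + 3, size = 10L))
  for (j in 1:4) {
    if (rs[[j]]$degenerate) next
    expect_equal(rs[[j]]$region$origin, unname(seg_origins[j, ]))
  }
})

test_that("the cascade is deterministic and containment holds on shifts", {
  cfg <- mini_phantom_config(motion = "translation", translation = c(2, -3),
                             frames = 2L)
  f0 <- render_tag_image(cfg, 0)
  f1 <- render_tag_image(cfg, 1)
  cc1 <- htm_correspondences(f0, f1)
  cc2 <- htm_correspondences(f0, f1)
  expect_identical(cc1, cc2)
  # displacements bounded by search geometry: radius + cascade margins
  d <- pmax(abs(cc1$ref_row - cc1$mov_row), abs(cc1$ref_col - cc1$mov_col))
  lim <- 8 + 4 * attr(cc1, "cfg")$overlap_margin
  expect_true(all(d <= lim))
})

test_that("mismatched image dimensions are rejected", {
  expect_error(htm_correspondences(matrix(0, 32, 32), matrix(0, 32, 48)),
               "identical dimensions")
})

test_that("correspondences survive a CSV round trip", {
  cfg <- mini_phantom_config()
  f0 <- render_tag_image(cfg, 0)
  cc <- htm_correspondences(f0, f0)
  tmp <- tempfile(fileext = ".csv")
  write_correspondences(cc, tmp)
  back <- read_correspondences(tmp)
  expect_equal(back$mov_row, cc$mov_row)
  expect_equal(back$ref_col, cc$ref_col, tolerance = 1e-9)
  expect_equal(back$flag, cc$flag)
  expect_error(read_correspondences(write_points(cbind(1, 2),
               tempfile(fileext = ".csv"))), "columns")
})
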