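test_that("a full synthetic table parses to 68 cortical thickness rows", {
  tab <- synthetic_region_stats("S001", seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_region_stats(tab, dir, "S001")
  parsed <- parse_region_stats(paths, "S001")
  expect_identical(sum(!is.na(parsed$thickness_mm)), 68L)
  expect_identical(nrow(parsed), 72L)   # + 4 subcortical volumes
  expect_equal(attr(parsed, "icv_mm3"), 1.45e6)
})

test_that("write/parse round-trip reproduces the table", {
  tab <- synthetic_region_stats("S002", seed = 8)
  dir <- withr::local_tempdir()
  parsed <- parse_region_stats(write_region_stats(tab, dir, "S002"))
  ord <- function(x) {
    x <- as.data.frame(x)[order(x$hemi, x$region), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(parsed), ord(tab), ignore_attr = TRUE)
})

test_that("schema violations and malformed rows are rejected with context", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "nothick.stats")
  writeLines(c("# hemi lh", "# ColHeaders StructName SurfArea GrayVol",
               "entorhinal 500 1200"), f1)
  expect_error(parse_region_stats(f1), "ThickAvg|Volume_mm3")
  f2 <- file.path(dir, "short.stats")
  writeLines(c("# hemi lh",
               "# ColHeaders StructName SurfArea GrayVol ThickAvg",
               "entorhinal 500 1200 3.1", "fusiform 900 2100"), f2)
  expect_error(parse_region_stats(f2), "line 4")
  f3 <- file.path(dir, "noheader.stats")
  writeLines("entorhinal 500 1200 3.1", f3)
  expect_error(parse_region_stats(f3), "ColHeaders")
})

test_that("implausible thickness values raise a warning, not an error", {
  tab <- synthetic_region_stats("S003", seed = 1)
  dir <- withr::local_tempdir()
  tab$thickness_mm[1] <- 9.5
  paths <- write_region_stats(tab, dir, "S003")
  expect_warning(parse_region_stats(paths), "plausibility")
})

test_that("composite thickness is the area-weighted mean, averaged over sides", {
  tab <- data.frame(
    hemi = rep(c("lh", "rh"), each = 2),
    region = rep(c("a", "b"), 2),
    volume_mm3 = c(200, 900, 200, 900),
    thickness_mm = c(2, 3, 2, 3),
    surf_area_mm2 = c(100, 300, 100, 300))
  def <- list(voi_definition("ab", c("a", "b"), "thickness"))
  expect_equal(unname(compute_composite_vois(tab, def)), 2.75)
  expect_equal(unname(compute_composite_vois(tab, def,
                                             weighted = FALSE)), 2.5)
  # constancy: equal member thicknesses ignore the weights entirely
  tab$thickness_mm <- 2.2
  expect_equal(unname(compute_composite_vois(tab, def)), 2.2)
})

test_that("composites respect member bounds and L/R averaging", {
  tab <- synthetic_region_stats("S004", seed = 12)
  defs <- default_voi_definitions()
  vals <- compute_composite_vois(tab, defs)
  for (nm in c("temporal_meta", "frontal")) {
    members <- defs[[nm]]$members
    sub <- tab[tab$region %in% members, ]
    expect_gte(vals[[nm]], min(sub$thickness_mm))
    expect_lte(vals[[nm]], max(sub$thickness_mm))
  }
  # identical hemispheres: L/R averaging commutes with the weighted mean
  sym <- tab
  rh <- sym$hemi == "rh"
  lh_rows <- match(paste(sym$region[rh]), paste(sym$region[!rh]))
  sym[rh, c("volume_mm3", "thickness_mm", "surf_area_mm2")] <-
    sym[!rh, ][lh_rows, c("volume_mm3", "thickness_mm", "surf_area_mm2")]
  vs <- compute_composite_vois(sym, defs["temporal_meta"])
  one <- sym[sym$hemi == "lh" &
               sym$region %in% defs$temporal_meta$members, ]
  expect_equal(unname(vs["temporal_meta"]),
               stats::weighted.mean(one$thickness_mm, one$surf_area_mm2))
})

test_that("singleton volume VOIs pass through the parsed value with ICV per mil", {
  tab <- synthetic_region_stats("S005", seed = 20)
  def <- list(voi_definition("hippocampus", "Hippocampus", "volume"))
  vals <- compute_composite_vois(tab, def, icv_mm3 = 1.5e6)
  hv <- tab$volume_mm3[tab$region == "Hippocampus"]
  expect_equal(unname(vals["hippocampus"]), mean(hv))
  expect_equal(unname(vals["hippocampus_norm"]), mean(hv) / 1.5e6 * 1000)
})

test_that("a missing member region is an error naming it", {
  tab <- synthetic_region_stats("S006", seed = 2)
  def <- list(voi_definition("bad", c("entorhinal", "nonexistent"),
                             "thickness"))
  expect_error(compute_composite_vois(tab, def), "nonexistent")
})
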