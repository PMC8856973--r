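# shared fixtures: everything is generated in code at test time

# records over custom k-rank vocabularies, possibly with empty ranks
random_ranked_records <- function(n, kx, ky, allow_empty = TRUE) {
  x_labels <- paste0("x", seq_len(kx))
  y_labels <- paste0("y", seq_len(ky))
  px <- stats::runif(kx)
  py <- stats::runif(ky)
  if (allow_empty && kx > 2 && stats::runif(1) < 0.3) px[sample(kx, 1)] <- 0
  list(
    records = data.frame(
      id = sprintf("t%04d", seq_len(n)),
      xvar = sample(x_labels, n, replace = TRUE, prob = px / sum(px)),
      yvar = sample(y_labels, n, replace = TRUE, prob = py / sum(py)),
      weight = stats::runif(n, 0.5, 2),
      stringsAsFactors = FALSE
    ),
    x_spec = ordered_category_spec(x_labels),
    y_spec = ordered_category_spec(y_labels)
  )
}

# independent cumulative-sum pairing: the brute-force oracle for the
# marginal (paper-mode) curve, computed without touching the table code path
oracle_paper_vertices <- function(records, x_spec, y_spec) {
  cum_share <- function(values, labels) {
    freq <- vapply(labels,
                   function(l) sum(records$weight[values == l]), numeric(1))
    100 * cumsum(freq) / sum(freq)
  }
  p <- c(0, cum_share(records$xvar, x_spec$labels))
  L <- c(0, cum_share(records$yvar, y_spec$labels))
  keep <- c(diff(p) > 1e-12, TRUE)  # empty X ranks: keep the last vertex
  p <- p[keep]; L <- L[keep]
  L[1] <- 0  # the origin anchor always survives
  data.frame(p = p, L = L)
}

# random valid curve: strictly increasing p, nondecreasing L, anchored
random_curve <- function(max_vertices = 8) {
  k <- sample(2:max_vertices, 1)
  p <- sort(stats::runif(k - 1, 1, 99))
  L <- sort(stats::runif(k - 1, 0, 100))
  concentration_curve_points(c(0, p, 100), c(0, L, 100))
}

# small survey fixture with exact wealth counts poor/rich/richer/richest
records_with_wealth_counts <- function(counts) {
  wealth <- rep(wealth_levels(), counts)
  n <- length(wealth)
  data.frame(
    id = sprintf("w%03d", seq_len(n)),
    age = rep(40, n), sex = NA_character_, wealth = wealth,
    exposure_alcohol = rep(exposure_levels(), length.out = n),
    exposure_tobacco = rep(exposure_levels()[1], n),
    exposure_diet = rep(exposure_levels()[1], n),
    exposure_inactivity = rep(exposure_levels()[1], n),
    weight = rep(1, n),
    stringsAsFactors = FALSE
  )
}

expected_rank_score <- function(m, cum_weights = c(25, 50, 75, 100)) {
  as.vector(m %*% cum_weights)
}

# extract data polylines (only M/L commands) from an SVG written by the
# cairo device; returns a list of two-column vertex matrices. Text glyphs
# (curved paths) are excluded, so this captures the plotted geometry while
# ignoring font layout, which can vary with the system font cache.
svg_polylines <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  d <- xml2::xml_attr(xml2::xml_find_all(doc, ".//path"), "d")
  d <- d[grepl("^M [0-9. ]+(L [0-9. ]+)*$", d)]
  lapply(d, function(s) {
    nums <- as.numeric(strsplit(gsub("[ML]", "", s), "\\s+")[[1]])
    nums <- nums[!is.na(nums)]
    matrix(nums, ncol = 2, byrow = TRUE)
  })
}

# polylines of a concentration figure in data units: the 45-degree
# reference segment, whose data coordinates are (0,0)-(100,100) by
# construction, pins down the panel's affine transform, making the
# comparison independent of text-driven layout shifts
svg_data_geometry <- function(path) {
  polys <- svg_polylines(path)
  diag_i <- which(vapply(polys, function(m) {
    nrow(m) == 2 && abs(diff(m[, 1])) > 100 && abs(diff(m[, 2])) > 100
  }, logical(1)))[1]
  ref <- polys[[diag_i]]
  # keep only panel-interior geometry; tick marks protrude outside the
  # panel and have fixed device-unit lengths that do not rescale
  inside <- vapply(polys, function(m) {
    all(m[, 1] >= min(ref[, 1]) - 0.5 & m[, 1] <= max(ref[, 1]) + 0.5 &
          m[, 2] >= min(ref[, 2]) - 0.5 & m[, 2] <= max(ref[, 2]) + 0.5)
  }, logical(1))
  lapply(polys[inside], function(m) {
    cbind(100 * (m[, 1] - ref[1, 1]) / (ref[2, 1] - ref[1, 1]),
          100 * (m[, 2] - ref[1, 2]) / (ref[2, 2] - ref[1, 2]))
  })
}

# compare two pipeline output directories: data artifacts byte-identical,
# figures geometry-identical, manifests identical up to the timestamp
expect_same_run <- function(out1, out2) {
  files <- sort(basename(list.files(out1)))
  testthat::expect_identical(files, sort(basename(list.files(out2))))
  for (f in setdiff(files, c("manifest.json", grep("\\.(svg|png)$", files,
                                                   value = TRUE)))) {
    testthat::expect_identical(readBin(file.path(out1, f), "raw", 1e7),
                               readBin(file.path(out2, f), "raw", 1e7),
                               label = f)
  }
  for (f in grep("\\.svg$", files, value = TRUE)) {
    testthat::expect_equal(svg_data_geometry(file.path(out1, f)),
                           svg_data_geometry(file.path(out2, f)),
                           tolerance = 1e-4, label = f)
  }
  m1 <- jsonlite::read_json(file.path(out1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(out2, "manifest.json"))
  m1$created <- m2$created <- NULL
  testthat::expect_identical(m1, m2)
}
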