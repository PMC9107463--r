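#' Read a cohort written by [write_cohort()]
#'
#' Reads the CSV manifest and the 8-bit grayscale (or RGB) PNG images in a
#' cohort directory. Colour images are converted to grayscale by luminance
#' averaging; polarity is inverted so that ink = 1 and background = 0 in
#' memory.
#'
#' @param directory Directory containing `manifest.csv` and the images.
#' @return A list with `pages` (list of `clock_raster`) and `manifest`
#'   (data frame).
#' @export
read_cohort <- function(directory) {
  manifest_path <- file.path(directory, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.csv in ", directory, call. = FALSE)
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  pages <- lapply(man$file, function(f) {
    px <- png::readPNG(file.path(directory, f))
    if (length(dim(px)) == 3L) {
      px <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3  # luminance average
    }
    clock_raster(1 - px)  # invert: ink (dark in file) becomes 1
  })
  list(pages = pages, manifest = man)
}

as_pixel_matrix <- function(page) {
  if (inherits(page, "clock_raster")) page$pixels else as.matrix(page)
}

#' Crop a page to its largest ink contour
#'
#' Binarizes the page (intensity > 0.5 counts as ink), labels connected
#' components with 8-connectivity, and returns the page cropped to the
#' bounding box of the component with the greatest pixel count — the
#' dominant drawing on the page.
#'
#' @param page A `clock_raster` or numeric matrix with intensities in
#'   `[0, 1]`, ink high.
#' @return A `clock_raster` holding the cropped sub-image (original
#'   intensities). The bounding box is attached as attribute `"bbox"`
#'   (`c(row1, row2, col1, col2)`).
#' @export
extract_sketch <- function(page) {
  px <- as_pixel_matrix(page)
  mask <- px > 0.5
  if (!any(mask)) {
    stop("no contour found: page has no ink above the binarization threshold",
         call. = FALSE)
  }
  lab <- .cc_label(mask)
  counts <- tabulate(lab[lab > 0L])
  biggest <- which.max(counts)
  idx <- which(lab == biggest, arr.ind = TRUE)
  r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
  c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
  out <- clock_raster(px[r1:r2, c1:c2, drop = FALSE])
  attr(out, "bbox") <- c(row1 = r1, row2 = r2, col1 = c1, col2 = c2)
  out
}

#' Size filter on a cropped sketch
#'
#' A crop is retained iff its bounding-box pixel count (`height * width`) is
#' strictly less than `max_pixels`. Oversized crops correspond to drawings
#' with excessive whitespace relative to ink, which destabilise
#' reconstruction training.
#'
#' @param cropped A `clock_raster` or matrix.
#' @param max_pixels Strict upper bound on `height * width`; default 40000
#'   (i.e. 200 x 200).
#' @return `TRUE` if retained, `FALSE` if discarded.
#' @export
size_filter <- function(cropped, max_pixels = 40000) {
  px <- as_pixel_matrix(cropped)
  (nrow(px) * ncol(px)) < max_pixels
}

# Exact area-average resampling operator mapping n input pixels to m output
# pixels: row i of the result holds the fractional overlap of output cell i
# with each input cell, normalised to sum to 1.
resize_operator <- function(n, m) {
  A <- matrix(0, m, n)
  scale <- n / m
  for (i in seq_len(m)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1L
    j1 <- min(n, ceiling(hi))
    for (j in j0:j1) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) A[i, j] <- overlap / scale
    }
  }
  A
}

#' Resize a crop to 100 x 100 and flatten to a 10,000-vector
#'
#' Resampling is area-preserving: each output pixel is the exact
#' pixel-overlap average of the input region it covers, computed with two
#' linear operators (`out = A \%*\% img \%*\% t(B)`). This downsamples thin
#' strokes without aliasing and is the identity on an input already at the
#' target size. Output values are clipped to `[0, 1]` and flattened
#' row-major.
#'
#' @param cropped A `clock_raster` or matrix.
#' @param target Output side length; default 100 (so vectors have length
#'   10,000).
#' @return A numeric vector of length `target^2` in `[0, 1]`.
#' @export
resize_flatten <- function(cropped, target = 100) {
  px <- as_pixel_matrix(cropped)
  A <- resize_operator(nrow(px), target)
  B <- resize_operator(ncol(px), target)
  out <- A %*% px %*% t(B)
  out <- pmin(pmax(out, 0), 1)
  as.numeric(t(out))  # row-major
}

#' Run the full preprocessing chain over a batch of pages
#'
#' Applies [extract_sketch()], [size_filter()] and [resize_flatten()] to
#' each page, with count accounting: every input page ends up as exactly one
#' of blank (no ink), filtered (oversized crop), or a produced vector.
#'
#' @param pages List of `clock_raster` pages (or matrices).
#' @param max_pixels,target Passed to [size_filter()] and
#'   [resize_flatten()].
#' @return A list with `vectors` (matrix, one row per retained page,
#'   `target^2` columns), `kept` (indices of retained pages), `n_blank`,
#'   `n_filtered`, `blank_idx`, `filtered_idx`.
#' @export
preprocess_pages <- function(pages, max_pixels = 40000, target = 100) {
  n <- length(pages)
  blank <- logical(n)
  filtered <- logical(n)
  vecs <- vector("list", n)
  for (i in seq_len(n)) {
    crop <- tryCatch(extract_sketch(pages[[i]]), error = function(e) NULL)
    if (is.null(crop)) {
      blank[i] <- TRUE
      next
    }
    if (!size_filter(crop, max_pixels)) {
      filtered[i] <- TRUE
      next
    }
    vecs[[i]] <- resize_flatten(crop, target)
  }
  kept <- which(!blank & !filtered)
  vectors <- if (length(kept)) {
    do.call(rbind, vecs[kept])
  } else {
    matrix(numeric(0), 0, target^2)
  }
  list(vectors = vectors, kept = kept,
       n_blank = sum(blank), n_filtered = sum(filtered),
       blank_idx = which(blank), filtered_idx = which(filtered))
}

#' Shuffle and split a labelled pool into fine-tune and test parts
#'
#' Applies a seeded uniform permutation, then partitions at the `ratio`
#' boundary with the floor convention on the test share: with `n` samples
#' and ratio `a:b`, the test part receives `floor(n * b / (a + b))` samples
#' and the fine-tune part the rest (113 samples at 3:1 gives 85/28).
#'
#' @param n Pool size, or a vector of labels of that length (used only for
#'   the empty-split warning).
#' @param ratio Two-element vector `c(fine_tune, test)`; default `c(3, 1)`.
#' @param seed Integer seed.
#' @return A list with integer index vectors `fine_tune` and `test`
#'   partitioning `seq_len(n)`.
#' @export
split_cohort <- function(n, ratio = c(3, 1), seed = 1) {
  labels <- NULL
  if (length(n) > 1L) {
    labels <- n
    n <- length(n)
  }
  check_range(n, "n", 1, 1e9, integer = TRUE)
  stopifnot(length(ratio) == 2L, all(ratio >= 0))
  n_test <- floor(n * ratio[2] / sum(ratio))
  perm <- with_seed(seed, sample.int(n))
  test <- sort(perm[seq_len(n_test)])
  fine_tune <- sort(perm[seq.int(n_test + 1L, length.out = n - n_test)])
  if (n_test == 0L || n_test == n) {
    warning("one split received zero samples", call. = FALSE)
  }
  if (!is.null(labels)) {
    for (part in list(fine_tune, test)) {
      if (length(part) && length(unique(labels[part])) < 2L &&
          length(unique(labels)) == 2L) {
        warning("a split contains a single class", call. = FALSE)
      }
    }
  }
  list(fine_tune = fine_tune, test = test)
}

#' Preprocess a rendered cohort into a labelled vector matrix
#'
#' Convenience wrapper: extracts the images of a [sample_cohort()] result,
#' runs [preprocess_pages()], and returns the vectors with the labels of the
#' retained items.
#'
#' @param items Cohort items from [sample_cohort()].
#' @param max_pixels,target Passed on to [preprocess_pages()].
#' @return List with `x` (matrix), `y` (labels of retained rows), `report`
#'   (the full [preprocess_pages()] result).
#' @export
preprocess_cohort <- function(items, max_pixels = 40000, target = 100) {
  pages <- lapply(items, `[[`, "image")
  rep_ <- preprocess_pages(pages, max_pixels, target)
  y <- vapply(items, `[[`, numeric(1), "label")[rep_$kept]
  list(x = rep_$vectors, y = y, report = rep_)
}
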