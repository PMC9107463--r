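#' Generative factors of a synthetic clock drawing
#'
#' Bundles the ground-truth parameters from which [render_clock()] draws one
#' clock face. The factors mirror the drawing features a two-latent
#' representation of clock sketches is known to pick up: face size,
#' eccentricity of the face, hand geometry (length and displacement of the
#' intersection point from the face centre), completeness of the drawn
#' boundary, plus nuisance parameters (margin, stroke width, pixel noise).
#'
#' @param face_radius Face radius as a fraction of the canvas side, in
#'   `[0.1, 0.45]`.
#' @param eccentricity Deviation of the face from a circle, in `[0, 0.6]`:
#'   the semi-axes are `r * (1 +/- eccentricity / 2)`.
#' @param eccentricity_angle Orientation of the major axis, radians in
#'   `[0, pi)`.
#' @param hand_offset Displacement of the hand-intersection point from the
#'   face centre, as a fraction of the radius, in `[0, 0.8]`.
#' @param hour_hand_len,minute_hand_len Hand lengths as fractions of the
#'   radius, in `(0, 1]`. Ignored when `hands_present` is `FALSE`.
#' @param hands_present Draw the two hands ("ten after eleven")?
#' @param boundary_completeness Fraction of the face perimeter actually
#'   drawn, in `[0.3, 1]`.
#' @param digits_present Draw the twelve hour ticks?
#' @param stroke_width Stroke width in pixels, `>= 1`.
#' @param margin Whitespace border fraction, in `[0, 0.6]`; enlarges the
#'   page around the drawing (the rendered page side is
#'   `canvas_px * (1 + margin)`), so contour cropping has real work to do.
#' @param noise_level Per-pixel flip probability, in `[0, 0.05]`.
#'
#' @return An object of class `clock_factors` (a named list).
#' @seealso [render_clock()], [sample_cohort()]
#' @export
#' @examples
#' f <- clock_factors(face_radius = 0.3, eccentricity = 0.2)
#' img <- render_clock(f, canvas_px = 128, seed = 1)
clock_factors <- function(face_radius = 0.32,
                          eccentricity = 0,
                          eccentricity_angle = 0,
                          hand_offset = 0,
                          hour_hand_len = 0.5,
                          minute_hand_len = 0.85,
                          hands_present = TRUE,
                          boundary_completeness = 1,
                          digits_present = TRUE,
                          stroke_width = 2,
                          margin = 0.15,
                          noise_level = 0) {
  check_range(face_radius, "face_radius", 0.1, 0.45)
  check_range(eccentricity, "eccentricity", 0, 0.6)
  check_range(eccentricity_angle, "eccentricity_angle", 0, pi)
  check_range(hand_offset, "hand_offset", 0, 0.8)
  check_range(hour_hand_len, "hour_hand_len", 1e-6, 1)
  check_range(minute_hand_len, "minute_hand_len", 1e-6, 1)
  check_flag(hands_present, "hands_present")
  check_range(boundary_completeness, "boundary_completeness", 0.3, 1)
  check_flag(digits_present, "digits_present")
  check_range(stroke_width, "stroke_width", 1, 10)
  check_range(margin, "margin", 0, 0.6)
  check_range(noise_level, "noise_level", 0, 0.05)
  structure(
    list(face_radius = face_radius,
         eccentricity = eccentricity,
         eccentricity_angle = eccentricity_angle,
         hand_offset = hand_offset,
         hour_hand_len = hour_hand_len,
         minute_hand_len = minute_hand_len,
         hands_present = hands_present,
         boundary_completeness = boundary_completeness,
         digits_present = digits_present,
         stroke_width = stroke_width,
         margin = margin,
         noise_level = noise_level),
    class = "clock_factors"
  )
}

factor_field_names <- function() {
  c("face_radius", "eccentricity", "eccentricity_angle", "hand_offset",
    "hour_hand_len", "minute_hand_len", "hands_present",
    "boundary_completeness", "digits_present", "stroke_width", "margin",
    "noise_level")
}

clock_raster <- function(pixels) {
  stopifnot(is.matrix(pixels))
  structure(list(pixels = pixels,
                 height = nrow(pixels),
                 width = ncol(pixels)),
            class = "clock_raster")
}

#' @export
print.clock_raster <- function(x, ...) {
  cat(sprintf("<clock_raster %d x %d, %d ink pixels>\n",
              x$height, x$width, sum(x$pixels > 0.5)))
  invisible(x)
}

# Stamp a polyline given as continuous (x, y) coordinates onto `canvas`
# with a disc brush of diameter `width` pixels. Returns the canvas.
stamp_points <- function(canvas, xs, ys, width) {
  n <- nrow(canvas)
  r <- width / 2
  span <- seq(-floor(r), floor(r))
  offs <- expand.grid(dr = span, dc = span)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, , drop = FALSE]
  rows <- round(ys)
  cols <- round(xs)
  rr <- outer(rows, offs$dr, `+`)
  cc <- outer(cols, offs$dc, `+`)
  keep <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
  canvas[cbind(rr[keep], cc[keep])] <- 1
  canvas
}

# Sample a parametric curve densely enough that consecutive points are
# < 0.5 px apart, so the stamped stroke has no gaps.
curve_points <- function(fx, fy, t0, t1, approx_len) {
  m <- max(8L, ceiling(approx_len / 0.4))
  t <- seq(t0, t1, length.out = m)
  list(x = fx(t), y = fy(t))
}

#' Render one synthetic clock drawing
#'
#' Draws a clock face (a possibly eccentric, possibly incomplete ellipse),
#' optional hour ticks, and optional hands set to "ten after eleven" whose
#' intersection point can be displaced from the face centre. Ink is encoded
#' as intensity 1 on a 0 background. The face radius is
#' `face_radius * canvas_px`; the page itself is enlarged by the `margin`
#' fraction and the face centre is jittered within it (seeded), so that
#' downstream contour cropping is exercised. The actual centre is returned
#' in the `"center"` attribute as `c(x, y)`.
#'
#' @param factors A [clock_factors()] object.
#' @param canvas_px Nominal canvas side length in pixels, `>= 64`.
#' @param seed Integer seed; the render is a pure function of
#'   `(factors, canvas_px, seed)`.
#'
#' @return A `clock_raster`: list with `pixels` (a square matrix of side
#'   `round(canvas_px * (1 + margin))` with values in `[0, 1]`), `height`,
#'   `width`.
#' @export
render_clock <- function(factors, canvas_px = 256, seed = 0) {
  if (!inherits(factors, "clock_factors")) {
    factors <- do.call(clock_factors, as.list(factors)[factor_field_names()])
  }
  check_range(canvas_px, "canvas_px", 64, 4096, integer = TRUE)
  with_seed(seed, {
    f <- factors
    # margin adds a whitespace border: the page grows beyond the nominal
    # canvas, and the drawing's own size stays proportional to face_radius
    n <- as.integer(round(canvas_px * (1 + f$margin)))
    canvas <- matrix(0, n, n)
    r <- f$face_radius * canvas_px
    a <- r * (1 + f$eccentricity / 2)
    b <- r * (1 - f$eccentricity / 2)
    extent <- 1.05 * a + f$stroke_width + 2  # hands are clipped to the face
    slack <- max(0, n / 2 - extent)
    cx <- n / 2 + stats::runif(1, -slack, slack)
    cy <- n / 2 + stats::runif(1, -slack, slack)

    rot <- f$eccentricity_angle
    ell_x <- function(t) cx + a * cos(t) * cos(rot) - b * sin(t) * sin(rot)
    ell_y <- function(t) cy + a * cos(t) * sin(rot) + b * sin(t) * cos(rot)

    # face boundary: arc of `boundary_completeness` of the perimeter,
    # starting at a seeded angle
    t0 <- stats::runif(1, 0, 2 * pi)
    arc <- 2 * pi * f$boundary_completeness
    p <- curve_points(ell_x, ell_y, t0, t0 + arc, approx_len = arc * a)
    canvas <- stamp_points(canvas, p$x, p$y, f$stroke_width)

    if (f$digits_present) {
      # hour marks as short radial ticks just inside the boundary
      for (k in 0:11) {
        t <- pi / 2 - k * pi / 6  # parameter chosen on the unrotated ellipse
        for (fr in c(0.82, 0.88, 0.94)) {
          px <- cx + fr * (a * cos(t) * cos(rot) - b * sin(t) * sin(rot))
          py <- cy + fr * (a * cos(t) * sin(rot) + b * sin(t) * cos(rot))
          canvas <- stamp_points(canvas, px, py, f$stroke_width)
        }
      }
    }

    if (f$hands_present) {
      # intersection point displaced from the centre in a seeded direction
      phi <- stats::runif(1, 0, 2 * pi)
      hx <- cx + f$hand_offset * r * cos(phi)
      hy <- cy + f$hand_offset * r * sin(phi)
      # clock angles measured clockwise from 12; screen rows grow downward.
      # Hands are clipped to the face: drawers keep hands inside the dial,
      # so a displaced intersection shortens them rather than poking out.
      inside_face <- function(x, y) {
        u <- ((x - cx) * cos(rot) + (y - cy) * sin(rot)) / a
        v <- (-(x - cx) * sin(rot) + (y - cy) * cos(rot)) / b
        u^2 + v^2 <= 1.05^2
      }
      draw_hand <- function(theta_deg, len) {
        th <- theta_deg * pi / 180
        ex <- hx + len * r * sin(th)
        ey <- hy - len * r * cos(th)
        q <- curve_points(function(t) hx + t * (ex - hx),
                          function(t) hy + t * (ey - hy),
                          0, 1, approx_len = len * r)
        keep <- inside_face(q$x, q$y)
        if (!any(keep)) return(canvas)
        stamp_points(canvas, q$x[keep], q$y[keep], f$stroke_width)
      }
      canvas <- draw_hand(335, f$hour_hand_len)   # hour hand toward 11
      canvas <- draw_hand(60, f$minute_hand_len)  # minute hand toward 2
    }

    if (f$noise_level > 0) {
      flip <- matrix(stats::runif(n * n) < f$noise_level, n, n)
      canvas <- abs(canvas - as.numeric(flip))
    }

    out <- clock_raster(canvas)
    attr(out, "center") <- c(x = cx, y = cy)
    out
  })
}

#' Per-class factor distributions for cohort sampling
#'
#' Default distribution of [clock_factors()] fields for a "control"-like or a
#' "dementia"-like drawing population. Controls are tightly concentrated near
#' a circular, complete, centred clock; the dementia class has widened
#' distributions (smaller and more variable faces, more eccentricity, larger
#' hand displacement) plus discrete anomaly modes — missing hands, broken
#' boundary, strong eccentricity — each at probability 0.3. Scan nuisances
#' (margin, pixel noise) are drawn per item; pixel noise uses the same
#' uniform range for both classes so that scanner artefacts carry no label
#' information.
#'
#' @param class `"control"` or `"dementia"`.
#' @return A named list of location/scale pairs, anomaly probabilities and
#'   fixed nuisance settings, consumed by [cohort_spec()].
#' @export
default_class_spec <- function(class = c("control", "dementia")) {
  class <- match.arg(class)
  if (class == "control") {
    list(face_radius = c(0.30, 0.07),
         eccentricity = c(0.05, 0.05),
         hand_offset = c(0.05, 0.05),
         hour_hand_len = c(0.50, 0.05),
         minute_hand_len = c(0.85, 0.05),
         boundary_completeness = c(1.0, 0.02),
         digits_prob = 0.9,
         margin = c(0.05, 0.35),
         stroke_width = 2,
         noise_level = c(0, 0.008),
         p_missing_hands = 0.02,
         p_broken_boundary = 0.02,
         p_high_eccentricity = 0.02)
  } else {
    list(face_radius = c(0.26, 0.09),
         eccentricity = c(0.25, 0.15),
         hand_offset = c(0.25, 0.20),
         hour_hand_len = c(0.40, 0.15),
         minute_hand_len = c(0.70, 0.20),
         boundary_completeness = c(0.90, 0.15),
         digits_prob = 0.7,
         margin = c(0.05, 0.45),
         stroke_width = 2,
         noise_level = c(0, 0.008),
         p_missing_hands = 0.3,
         p_broken_boundary = 0.3,
         p_high_eccentricity = 0.3)
  }
}

#' Specification of a two-class synthetic cohort
#'
#' @param n_control,n_dementia Number of label-0 (control) and label-1
#'   (dementia) drawings.
#' @param seed Integer seed controlling both factor sampling and rendering.
#' @param control,dementia Class distributions, as from
#'   [default_class_spec()].
#' @param canvas_px Canvas side length passed to [render_clock()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control, n_dementia, seed = 1,
                        control = default_class_spec("control"),
                        dementia = default_class_spec("dementia"),
                        canvas_px = 256) {
  check_range(n_control, "n_control", 0, 1e6, integer = TRUE)
  check_range(n_dementia, "n_dementia", 0, 1e6, integer = TRUE)
  if (n_control + n_dementia < 2) {
    stop("cohort must contain at least 2 drawings", call. = FALSE)
  }
  anomaly <- c("p_missing_hands", "p_broken_boundary", "p_high_eccentricity")
  if (any(unlist(dementia[anomaly]) < unlist(control[anomaly]))) {
    stop("dementia-class anomaly probabilities must be >= control-class ones",
         call. = FALSE)
  }
  structure(list(n_control = as.integer(n_control),
                 n_dementia = as.integer(n_dementia),
                 seed = seed, control = control, dementia = dementia,
                 canvas_px = canvas_px),
            class = "cohort_spec")
}

sample_factors_one <- function(cs) {
  ecc <- if (stats::runif(1) < cs$p_high_eccentricity) {
    stats::runif(1, 0.35, 0.6)
  } else {
    rnorm_trunc(1, cs$eccentricity[1], cs$eccentricity[2], 0, 0.6)
  }
  compl <- if (stats::runif(1) < cs$p_broken_boundary) {
    stats::runif(1, 0.3, 0.7)
  } else {
    rnorm_trunc(1, cs$boundary_completeness[1], cs$boundary_completeness[2],
                0.3, 1)
  }
  clock_factors(
    face_radius = rnorm_trunc(1, cs$face_radius[1], cs$face_radius[2],
                              0.1, 0.45),
    eccentricity = ecc,
    eccentricity_angle = stats::runif(1, 0, pi * (1 - 1e-9)),
    hand_offset = rnorm_trunc(1, cs$hand_offset[1], cs$hand_offset[2], 0, 0.8),
    hour_hand_len = rnorm_trunc(1, cs$hour_hand_len[1], cs$hour_hand_len[2],
                                0.1, 1),
    minute_hand_len = rnorm_trunc(1, cs$minute_hand_len[1],
                                  cs$minute_hand_len[2], 0.1, 1),
    hands_present = stats::runif(1) >= cs$p_missing_hands,
    boundary_completeness = compl,
    digits_present = stats::runif(1) < cs$digits_prob,
    stroke_width = cs$stroke_width,
    margin = stats::runif(1, cs$margin[1], cs$margin[2]),
    noise_level = stats::runif(1, cs$noise_level[1], cs$noise_level[2])
  )
}

#' Sample a labelled cohort of synthetic clock drawings
#'
#' Draws `n_control` label-0 and `n_dementia` label-1 clocks from the class
#' distributions in `spec` and renders each one. Reproducible: the result is
#' a pure function of `spec` (which includes its seed).
#'
#' @param spec A [cohort_spec()].
#' @return A list of items, each a list with elements `factors`
#'   ([clock_factors()]), `image` (`clock_raster`) and `label` (0 control /
#'   1 dementia).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_control + spec$n_dementia
  labels <- rep(c(0L, 1L), c(spec$n_control, spec$n_dementia))
  seeds <- derive_seeds(spec$seed, n + 1L)
  items <- vector("list", n)
  with_seed(seeds[n + 1L], {
    for (i in seq_len(n)) {
      cs <- if (labels[i] == 0L) spec$control else spec$dementia
      fac <- sample_factors_one(cs)
      items[[i]] <- list(factors = fac,
                         image = render_clock(fac, spec$canvas_px, seeds[i]),
                         label = labels[i])
    }
  })
  items
}

#' Tabulate the generative factors of a cohort
#'
#' @param items A cohort as returned by [sample_cohort()].
#' @return A data frame with one row per item: all factor fields plus
#'   `label`.
#' @export
factor_table <- function(items) {
  if (length(items) == 0L) {
    cols <- c(factor_field_names(), "label")
    df <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(df) <- cols
    return(df)
  }
  rows <- lapply(items, function(it) {
    f <- it$factors
    data.frame(lapply(unclass(f), identity), label = it$label)
  })
  do.call(rbind, rows)
}

#' Write a cohort to disk as PNG images plus a CSV manifest
#'
#' Images are stored as 8-bit grayscale PNGs in the conventional
#' dark-ink-on-white polarity (file intensity = 1 - ink); [read_cohort()]
#' inverts back so that ink = 1 in memory. The manifest has columns
#' `file,label,split` followed by all factor fields.
#'
#' @param items A cohort from [sample_cohort()]; may be empty.
#' @param directory Output directory (created if needed).
#' @param split Optional character vector of split tags, recycled to the
#'   number of items; defaults to `NA`.
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(items, directory, split = NA_character_) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stop("cannot create directory: ", directory, call. = FALSE)
    }
  }
  n <- length(items)
  manifest_path <- file.path(directory, "manifest.csv")
  if (n == 0L) {
    man <- data.frame(file = character(0), label = integer(0),
                      split = character(0))
    for (fn in factor_field_names()) man[[fn]] <- numeric(0)
    utils::write.csv(man, manifest_path, row.names = FALSE)
    return(invisible(man))
  }
  split <- rep_len(as.character(split), n)
  files <- sprintf("clock_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    img <- 1 - items[[i]]$image$pixels  # dark ink on white in the file
    png::writePNG(img, file.path(directory, files[i]))
  }
  ft <- factor_table(items)
  man <- cbind(data.frame(file = files, label = ft$label, split = split),
               ft[factor_field_names()])
  utils::write.csv(man, manifest_path, row.names = FALSE)
  invisible(man)
}
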