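#' Traverse the latent plane on a regular grid
#'
#' Decodes every point of a `steps` x `steps` grid spanning `range` in both
#' latent dimensions. Following the usual presentation, Z0 (the first latent
#' dimension) runs along the horizontal axis and Z1 along the vertical axis
#' of the assembled montage, with Z1 increasing upward.
#'
#' @param params A trained `vae_params` (with `latent_dim = 2`).
#' @param steps Grid points per axis, `>= 2`; default 9 (step 1 over
#'   `[-4, 4]`).
#' @param range Two-element numeric range for both axes; default `c(-4, 4)`.
#' @param side Side length of each reconstruction when reshaped; default
#'   `sqrt(input_dim)`.
#' @return An object of class `traversal_grid`: list with `z0_values`,
#'   `z1_values`, `reconstructions` (a list of lists indexed
#'   `[[i_z0]][[j_z1]]`, each a `side` x `side` matrix) and `montage` (one
#'   large matrix with Z0 horizontal, Z1 vertical).
#' @export
traverse <- function(params, steps = 9, range = c(-4, 4), side = NULL) {
  check_range(steps, "steps", 2, 512, integer = TRUE)
  stopifnot(params$latent_dim == 2)
  if (is.null(side)) side <- as.integer(round(sqrt(params$input_dim)))
  stopifnot(side * side == params$input_dim)
  z0 <- seq(range[1], range[2], length.out = steps)
  z1 <- seq(range[1], range[2], length.out = steps)
  grid <- as.matrix(expand.grid(Z0 = z0, Z1 = z1))
  xh <- decode(params, grid)
  recon <- vector("list", steps)
  montage <- matrix(0, steps * side, steps * side)
  for (i in seq_len(steps)) {
    recon[[i]] <- vector("list", steps)
    for (j in seq_len(steps)) {
      row_idx <- (j - 1L) * steps + i  # expand.grid: Z0 varies fastest
      img <- matrix(xh[row_idx, ], side, side, byrow = TRUE)
      recon[[i]][[j]] <- img
      # montage: column block i = z0[i]; row block from top = largest z1
      rblock <- steps - j
      montage[(rblock * side + 1):((rblock + 1) * side),
              ((i - 1) * side + 1):(i * side)] <- img
    }
  }
  structure(list(z0_values = z0, z1_values = z1,
                 reconstructions = recon, montage = montage),
            class = "traversal_grid")
}

#' Write a traversal montage to a PNG file
#'
#' @param grid A `traversal_grid` from [traverse()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_traversal_png <- function(grid, path) {
  png::writePNG(grid$montage, path)
  invisible(path)
}

#' Project a cohort onto the latent plane
#'
#' Uses posterior means (no sampling), giving a deterministic 2-D embedding
#' suitable for plotting and for the kNN operationalization.
#'
#' @param params A trained `vae_params`.
#' @param x Matrix of flattened images (rows), possibly with zero rows.
#' @return A numeric matrix with columns `Z0`, `Z1` and one row per image.
#' @export
project_cohort <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0L) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("Z0", "Z1"))))
  }
  mu <- enc_forward(params, as_row_matrix(x, params$input_dim))$mean
  colnames(mu) <- c("Z0", "Z1")
  mu
}

#' Rank correlation between latent dimensions and generative factors
#'
#' Computes the Spearman correlation of each latent dimension with each
#' numeric generative-factor column. Constant columns have no defined rank
#' correlation and are reported as `NA` rather than zero.
#'
#' @param factors A data frame of generative factors (e.g. from
#'   [factor_table()]); logical columns are coerced to 0/1.
#' @param latents Matrix of latent points (columns Z0, Z1), same number of
#'   rows.
#' @return An object of class `factor_correlation`: list with `rho` (2 x
#'   n_factors matrix, rows Z0/Z1), `n`.
#' @export
factor_correlation <- function(factors, latents) {
  stopifnot(nrow(factors) == nrow(latents), nrow(latents) >= 10)
  num <- as.data.frame(lapply(factors, function(col) {
    if (is.logical(col)) as.numeric(col) else suppressWarnings(as.numeric(col))
  }))
  keepable <- vapply(num, function(c) !all(is.na(c)), logical(1))
  num <- num[keepable]
  rho <- matrix(NA_real_, 2, ncol(num),
                dimnames = list(c("Z0", "Z1"), names(num)))
  for (j in seq_along(num)) {
    col <- num[[j]]
    if (length(unique(col)) < 2L) next  # constant: undefined, stays NA
    rho[1, j] <- stats::cor(latents[, 1], col, method = "spearman")
    rho[2, j] <- stats::cor(latents[, 2], col, method = "spearman")
  }
  structure(list(rho = rho, n = nrow(latents)), class = "factor_correlation")
}

#' @export
print.factor_correlation <- function(x, ...) {
  cat(sprintf("<factor_correlation over n = %d samples>\n", x$n))
  print(round(x$rho, 3))
  invisible(x)
}
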