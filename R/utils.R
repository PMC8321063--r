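# internal helpers shared across modules

# validate an n x 3 coordinate set coming in as tibble/data.frame with x,y,z
as_xyz_matrix <- function(cloud, arg = "cloud") {
  if (is.matrix(cloud)) {
    if (ncol(cloud) != 3) abort(sprintf("`%s` matrix must have 3 columns.", arg))
    m <- cloud
  } else if (is.data.frame(cloud)) {
    missing_cols <- setdiff(c("x", "y", "z"), names(cloud))
    if (length(missing_cols) > 0) {
      abort(sprintf("`%s` must have columns x, y, z (missing: %s).",
                    arg, paste(missing_cols, collapse = ", ")))
    }
    m <- cbind(cloud$x, cloud$y, cloud$z)
  } else {
    abort(sprintf("`%s` must be a data frame with x/y/z or an n x 3 matrix.", arg))
  }
  storage.mode(m) <- "double"
  if (nrow(m) < 1) abort(sprintf("`%s` is empty.", arg))
  if (!all(is.finite(m))) abort(sprintf("`%s` contains non-finite coordinates.", arg))
  dimnames(m) <- NULL
  m
}

xyz_tibble <- function(m, template = NULL) {
  out <- tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
  if (!is.null(template) && is.data.frame(template)) {
    extra <- setdiff(names(template), c("x", "y", "z"))
    for (col in extra) out[[col]] <- template[[col]]
  }
  out
}

# deterministic child seeds below 2^31 derived from one user seed
derive_seed <- function(seed, index) {
  (as.integer(seed) * 7919L + as.integer(index) * 104729L) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
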