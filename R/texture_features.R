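#' Texture feature names
#'
#' The 31 texture features extracted per (ROI, color component): 13 histogram
#' statistics (HS), 7 gray-level run-length matrix (GLRLM) features, and 11
#' gray-level co-occurrence matrix (GLCM / Haralick) features.
#'
#' @return named list with character vectors `hs`, `glrlm`, `glcm`.
#' @export
texture_feature_names <- function() {
  list(
    hs = c(
      "Mean", "Variance", "Skewness", "Kurtosis",
      "Perc01", "Perc10", "Perc50", "Perc90", "Perc99",
      "Domn01", "Domn10", "Maxm01", "Maxm10"
    ),
    glrlm = c("GLN", "RLN", "LRE", "SRE", "Fraction", "MRLN", "MGLN"),
    glcm = c(
      "AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDefMom",
      "SumAverg", "SumVarnc", "SumEntrp", "Entropy", "DifVarnc", "DifEntrp"
    )
  )
}

#' Normalized gray-level histogram
#'
#' H(k) = (number of member pixels with gray level k) / (member pixel count),
#' for k = 0 .. 2^bits - 1.
#'
#' @param values integer vector of ROI member pixel values.
#' @param bits gray-level depth n; levels run 0..2^n-1 (default 8).
#' @return object of class `gl_histogram`: list with `h` (probabilities,
#'   length 2^bits), `levels` (0-based), `pixel_count`, `bits`.
#' @export
compute_histogram <- function(values, bits = 8) {
  if (length(values) == 0) stop("no pixel values supplied")
  k_max <- 2^bits - 1
  if (any(values < 0 | values > k_max)) {
    stop("pixel values outside 0..", k_max)
  }
  counts <- tabulate(as.integer(values) + 1L, nbins = k_max + 1L)
  structure(
    list(
      h = counts / length(values), levels = 0:k_max,
      pixel_count = length(values), bits = bits
    ),
    class = "gl_histogram"
  )
}

#' First-order histogram statistics (13 HS features)
#'
#' Moments of the normalized histogram plus distribution landmarks:
#' * `Mean`, `Variance`: first two moments over gray level k.
#' * `Skewness`, `Kurtosis`: standardized third and fourth central moments
#'   (excess kurtosis); both defined as 0 for a zero-variance histogram.
#' * `PercXX`: smallest gray level at which the cumulative histogram reaches
#'   XX/100.
#' * `Domn01`: the mode (smallest gray level attaining max H).
#' * `Domn10`: smallest start of the `window`-bin interval with maximal summed
#'   probability.
#' * `Maxm01`: max H(k); `Maxm10`: maximal `window`-bin moving sum of H.
#'
#' @param hist a `gl_histogram`.
#' @param window moving-sum window r in bins for the "10"-suffixed features
#'   (default 10).
#' @return named numeric vector of the 13 HS features.
#' @export
hs_features <- function(hist, window = 10) {
  stopifnot(inherits(hist, "gl_histogram"))
  h <- hist$h
  k <- hist$levels
  m <- sum(k * h)
  v <- sum((k - m)^2 * h)
  if (v > 0) {
    skew <- sum((k - m)^3 * h) / v^1.5
    kurt <- sum((k - m)^4 * h) / v^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  cum <- cumsum(h)
  perc <- function(q) k[which(cum >= q - 1e-12)[1]]
  nk <- length(h)
  r <- min(window, nk)
  # direct window sums: cumulative-difference tricks break exact ties and
  # with them the smallest-index tie rule for Domn10
  moving <- vapply(seq_len(nk - r + 1), function(s) sum(h[s:(s + r - 1)]),
                   numeric(1))
  c(
    Mean = m, Variance = v, Skewness = skew, Kurtosis = kurt,
    Perc01 = perc(0.01), Perc10 = perc(0.10), Perc50 = perc(0.50),
    Perc90 = perc(0.90), Perc99 = perc(0.99),
    Domn01 = k[which.max(h)], Domn10 = k[which.max(moving)],
    Maxm01 = max(h), Maxm10 = max(moving)
  )
}

direction_offset <- function(direction, d = 1L) {
  switch(as.character(direction),
    "0" = c(0L, d),
    "45" = c(-d, d),
    "90" = c(-d, 0L),
    "135" = c(-d, -d),
    stop("direction must be one of 0, 45, 90, 135 (degrees)")
  )
}

# Split a masked plane into scan lines along a direction; non-member pixels
# are NA and terminate runs/pairs.
scan_lines <- function(plane, mask, direction) {
  view <- plane
  if (!is.null(mask)) view[!mask$membership] <- NA
  nr <- nrow(view)
  nc <- ncol(view)
  switch(as.character(direction),
    "0" = lapply(seq_len(nr), function(i) view[i, ]),
    "90" = lapply(seq_len(nc), function(j) view[, j]),
    "45" = lapply(seq_len(nr + nc - 1L), function(s) {
      # anti-diagonals: row + col constant; traverse up-right
      i <- min(s, nr):max(1L, s - nc + 1L)
      view[cbind(i, s - i + 1L)]
    }),
    "135" = lapply(seq_len(nr + nc - 1L), function(s) {
      # diagonals: row - col constant; traverse down-right
      off <- s - nc
      j <- max(1L, 1L - off):min(nc, nr - off)
      view[cbind(j + off, j)]
    }),
    stop("direction must be one of 0, 45, 90, 135 (degrees)")
  )
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along scan lines in the given
#' direction. Non-member pixels break scan lines, so only runs wholly inside
#' the ROI are counted. Entry `counts[i+1, j]` is the number of runs of gray
#' level i with length j.
#'
#' @param plane integer matrix of gray levels 0..2^bits-1.
#' @param mask optional `roi_mask`; `NULL` uses the full plane.
#' @param direction scan direction in degrees: 0, 45, 90 or 135.
#' @param bits gray-level depth (default 8).
#' @return object of class `glrlm`: list with `counts` (K x max-run-length),
#'   `direction`, `np` (total runs), `total_pixels`.
#' @export
build_glrlm <- function(plane, mask = NULL, direction = 0, bits = 8) {
  lines <- scan_lines(plane, mask, direction)
  flat <- unlist(lapply(lines, function(v) c(v, NA)), use.names = FALSE)
  runs <- rle(flat)
  keep <- !is.na(runs$values)
  lev <- runs$values[keep]
  len <- runs$lengths[keep]
  if (length(lev) == 0) stop("ROI contains no pixels")
  k_levels <- 2^bits
  max_len <- max(len)
  # accumulate (several runs may share level and length)
  tab <- tabulate((len - 1L) * k_levels + lev + 1L, nbins = k_levels * max_len)
  counts <- matrix(tab, nrow = k_levels, ncol = max_len)
  structure(
    list(
      counts = counts, direction = direction,
      np = sum(counts), total_pixels = sum(len)
    ),
    class = "glrlm"
  )
}

#' Run-length matrix features (7 GLRLM features)
#'
#' With p(i, j) the run counts, j the run length and np the total number of
#' runs:
#' * `GLN` gray-level non-uniformity, `RLN` run-length non-uniformity:
#'   squared marginal sums over 1/np.
#' * `LRE` long-run emphasis, `SRE` short-run emphasis: j^2-weighted moments.
#' * `Fraction`: runs per pixel, the fraction of the image in runs.
#' * `MRLN`, `MGLN`: the same squared marginals normalized by np^2.
#'
#' @param m a `glrlm`.
#' @return named numeric vector of the 7 GLRLM features.
#' @export
glrlm_features <- function(m) {
  stopifnot(inherits(m, "glrlm"))
  p <- m$counts
  np <- sum(p)
  if (np < 1) stop("empty run-length matrix")
  j <- seq_len(ncol(p))
  row_sums <- rowSums(p)
  col_sums <- colSums(p)
  c(
    GLN = sum(row_sums^2) / np,
    RLN = sum(col_sums^2) / np,
    LRE = sum(col_sums * j^2) / np,
    SRE = sum(col_sums / j^2) / np,
    Fraction = np / sum(col_sums * j),
    MRLN = sum(col_sums^2) / np^2,
    MGLN = sum(row_sums^2) / np^2
  )
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs at the given offset (distance d, direction)
#' with both pixels inside the ROI. Accumulation is symmetric: a pair with
#' levels (a, b) increments both p(a, b) and p(b, a), so the matrix is
#' symmetric by construction. With `normalize = TRUE` (default) entries are
#' divided by their total so they sum to 1.
#'
#' @inheritParams build_glrlm
#' @param d pixel distance (default 1).
#' @param normalize divide by the pair total (required by [glcm_features()]).
#' @return object of class `glcm`: list with `p` (K x K), `d`, `direction`,
#'   `symmetric`, `normalized`, `n_pairs` (ordered pairs counted, both
#'   orders).
#' @export
build_glcm <- function(plane, mask = NULL, d = 1, direction = 0, bits = 8,
                       normalize = TRUE) {
  stopifnot(d >= 1)
  off <- direction_offset(direction, as.integer(d))
  view <- plane
  if (!is.null(mask)) view[!mask$membership] <- NA
  nr <- nrow(view)
  nc <- ncol(view)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- view[r1, c1, drop = FALSE]
  b <- view[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no valid pixel pair in ROI for this offset")
  a <- as.integer(a[ok])
  b <- as.integer(b[ok])
  k_levels <- 2^bits
  tab <- tabulate(a * k_levels + b + 1L, nbins = k_levels^2)
  p <- matrix(tab, nrow = k_levels, ncol = k_levels, byrow = TRUE)
  p <- p + t(p)
  n_pairs <- sum(p)
  if (normalize) p <- p / n_pairs
  structure(
    list(
      p = p, d = d, direction = direction, symmetric = TRUE,
      normalized = normalize, n_pairs = n_pairs, bits = bits
    ),
    class = "glcm"
  )
}

#' Haralick co-occurrence features (11 GLCM features)
#'
#' Computed from a normalized symmetric co-occurrence matrix over 0-based
#' gray levels i, j, with 0*log(0) taken as 0:
#' * `AngScMom` (energy), `Contrast`, `Correlat` (Pearson correlation of the
#'   pair distribution; 0 for a degenerate marginal), `SumOfSqs` (variance of
#'   the row marginal), `InvDefMom` (homogeneity), `Entropy`.
#' * `SumAverg`, `SumVarnc`, `SumEntrp`: mean/variance/entropy of the i+j
#'   marginal.
#' * `DifVarnc`, `DifEntrp`: variance/entropy of the |i-j| marginal.
#'
#' @param m a normalized `glcm`.
#' @param log_base logarithm base for the entropy features (default 2).
#' @return named numeric vector of the 11 GLCM features.
#' @export
glcm_features <- function(m, log_base = 2) {
  stopifnot(inherits(m, "glcm"))
  if (!isTRUE(m$normalized)) stop("glcm_features requires a normalized matrix")
  nz <- which(m$p > 0)
  p <- m$p[nz]
  k_levels <- nrow(m$p)
  i <- (nz - 1L) %% k_levels          # 0-based row gray level
  j <- (nz - 1L) %/% k_levels         # 0-based col gray level
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p)
  var_j <- sum((j - mu_j)^2 * p)
  correlat <- if (var_i > 0 && var_j > 0) {
    (sum(i * j * p) - mu_i * mu_j) / sqrt(var_i * var_j)
  } else {
    0
  }
  # i+j and |i-j| marginal distributions
  p_sum <- rowsum(p, i + j)
  k_sum <- as.numeric(rownames(p_sum))
  p_sum <- as.numeric(p_sum)
  p_dif <- rowsum(p, abs(i - j))
  k_dif <- as.numeric(rownames(p_dif))
  p_dif <- as.numeric(p_dif)
  mu_sum <- sum(k_sum * p_sum)
  mu_dif <- sum(k_dif * p_dif)
  ent <- function(q) -sum(q * log(q, base = log_base))
  c(
    AngScMom = sum(p^2),
    Contrast = sum((i - j)^2 * p),
    Correlat = correlat,
    SumOfSqs = var_i,
    InvDefMom = sum(p / (1 + (i - j)^2)),
    SumAverg = mu_sum,
    SumVarnc = sum((k_sum - mu_sum)^2 * p_sum),
    SumEntrp = ent(p_sum),
    Entropy = ent(p),
    DifVarnc = sum((k_dif - mu_dif)^2 * p_dif),
    DifEntrp = ent(p_dif)
  )
}

#' Requantize a component plane to fewer gray levels
#'
#' Maps 8-bit values onto 2^bits levels by integer division, preserving
#' ordering. Used to shrink co-occurrence matrices in small-scale analyses.
#'
#' @param plane integer matrix with values 0..255.
#' @param bits target depth (<= 8).
#' @return integer matrix with values 0..2^bits-1.
#' @export
requantize_plane <- function(plane, bits) {
  stopifnot(bits >= 1, bits <= 8)
  out <- plane %/% as.integer(2^(8 - bits))
  storage.mode(out) <- "integer"
  out
}

#' Texture configuration
#'
#' Collects the tunable parameters of texture extraction.
#'
#' @param bits gray-level depth n (default 8, K = 256 levels).
#' @param d co-occurrence pixel distance (default 1).
#' @param glcm_directions directions (degrees) whose GLCM features are
#'   averaged (default all four).
#' @param glrlm_directions run-length directions averaged (default 0).
#' @param log_base entropy logarithm base (default 2).
#' @param window HS moving-sum window r (default 10 bins).
#' @return list of class `texture_config`.
#' @export
texture_config <- function(bits = 8, d = 1,
                           glcm_directions = c(0, 45, 90, 135),
                           glrlm_directions = 0,
                           log_base = 2, window = 10) {
  structure(
    list(
      bits = bits, d = d,
      glcm_directions = glcm_directions,
      glrlm_directions = glrlm_directions,
      log_base = log_base, window = window
    ),
    class = "texture_config"
  )
}

#' All 31 texture features of one (ROI, component) pair
#'
#' The plane must already hold values in 0..2^bits-1 for the configured
#' depth; [extract_all_features()] requantizes 8-bit component planes when a
#' coarser depth is configured.
#'
#' @param plane integer gray-level matrix (one color component).
#' @param mask optional `roi_mask`.
#' @param config a [texture_config()].
#' @return named numeric vector of length 31 in the canonical order
#'   (HS, GLRLM, GLCM).
#' @export
texture_features <- function(plane, mask = NULL, config = texture_config()) {
  values <- if (is.null(mask)) as.vector(plane) else plane[mask$membership]
  hs <- hs_features(compute_histogram(values, config$bits), config$window)
  glrlm <- rowMeans(vapply(
    config$glrlm_directions,
    function(dir) glrlm_features(build_glrlm(plane, mask, dir, config$bits)),
    numeric(7)
  ))
  glcm <- rowMeans(vapply(
    config$glcm_directions,
    function(dir) {
      glcm_features(
        build_glcm(plane, mask, config$d, dir, config$bits),
        config$log_base
      )
    },
    numeric(11)
  ))
  c(hs, glrlm, glcm)
}

#' Extract the full feature table of a study
#'
#' For every image, the 31 texture features are computed for each ROI x color
#' component (4 x 3 x 31 = 372 texture columns with the default four ROIs),
#' plus the three conventional thermal features per ROI whenever a
#' temperature field accompanies the image. Images whose extraction fails
#' (e.g. a missing ROI) are skipped with a warning and the run continues.
#'
#' @param images named list of `pseudocolor_image` objects, keyed by image id.
#' @param masks named list of `roi_mask` objects (shared across images), or a
#'   list of such lists keyed like `images`.
#' @param fields optional named list of temperature matrices keyed like
#'   `images`.
#' @param metadata optional data.frame with an `image_id` column; its columns
#'   are prepended to the output rows.
#' @param config a [texture_config()].
#' @return wide data.frame, one row per image; texture columns are named
#'   `ROI<label>_<component>_<feature>`, conventional columns
#'   `ROI<label>_<Taver|Tmax|Tmin>`.
#' @export
extract_all_features <- function(images, masks, fields = NULL,
                                 metadata = NULL, config = texture_config()) {
  stopifnot(length(images) >= 1)
  ids <- names(images)
  per_image_masks <- !inherits(masks[[1]], "roi_mask")
  rows <- lapply(ids, function(id) {
    res <- tryCatch(
      {
        mk <- if (per_image_masks) masks[[id]] else masks
        if (length(mk) == 0) stop("no ROI masks for image ", id)
        image_feature_row(images[[id]], mk, fields[[id]], config)
      },
      error = function(e) {
        warning("skipping image ", id, ": ", conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    res
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- as.data.frame(do.call(rbind, rows[keep]))
  out <- cbind(image_id = ids[keep], out, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    out <- merge(metadata, out, by = "image_id", sort = FALSE)
  }
  rownames(out) <- NULL
  out
}

image_feature_row <- function(image, masks, field, config) {
  comps <- decompose_components(image)
  if (config$bits < 8) {
    comps <- lapply(comps, requantize_plane, bits = config$bits)
  }
  cells <- list()
  for (mask in masks) {
    roi_tag <- paste0("ROI", mask$label)
    if (!is.null(field)) {
      conv <- conventional_features(field, mask)
      names(conv) <- paste0(roi_tag, "_", names(conv))
      cells[[length(cells) + 1]] <- conv
    }
    for (comp in names(comps)) {
      tf <- texture_features(comps[[comp]], mask, config)
      names(tf) <- paste0(roi_tag, "_", comp, "_", names(tf))
      cells[[length(cells) + 1]] <- tf
    }
  }
  unlist(cells)
}

#' Pivot a wide feature table to tidy long form
#'
#' @param wide output of [extract_all_features()].
#' @return data.frame with columns `image_id`, key columns, `roi`,
#'   `component`, `feature`, `value`; conventional columns get
#'   `component = NA`.
#' @export
feature_table_long <- function(wide) {
  feat_cols <- grep("^ROI[0-9]+_", names(wide), value = TRUE)
  key_cols <- setdiff(names(wide), feat_cols)
  parts <- strsplit(feat_cols, "_")
  roi <- vapply(parts, `[[`, character(1), 1)
  comp <- vapply(parts, function(p) if (length(p) == 3) p[[2]] else NA_character_, character(1))
  feat <- vapply(parts, function(p) p[[length(p)]], character(1))
  long <- do.call(rbind, lapply(seq_along(feat_cols), function(i) {
    data.frame(
      wide[key_cols],
      roi = roi[i], component = comp[i], feature = feat[i],
      value = wide[[feat_cols[i]]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(long) <- NULL
  long
}
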