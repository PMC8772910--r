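# Independent brute-force oracles for the texture features. These are written
# as naive enumerations (explicit loops, dictionary counting) and never share
# code with the package implementation.

oracle_histogram <- function(values, bits = 8) {
  k_max <- 2^bits - 1
  h <- numeric(k_max + 1)
  for (v in values) h[v + 1] <- h[v + 1] + 1
  h / length(values)
}

oracle_hs <- function(values, bits = 8, r = 10) {
  h <- oracle_histogram(values, bits)
  ks <- seq_along(h) - 1
  m <- sum(ks * h)
  v <- sum((ks - m)^2 * h)
  skew <- if (v > 0) sum((ks - m)^3 * h) / v^(3 / 2) else 0
  kurt <- if (v > 0) sum((ks - m)^4 * h) / v^2 - 3 else 0
  perc <- function(q) {
    acc <- 0
    for (k in ks) {
      acc <- acc + h[k + 1]
      if (acc >= q - 1e-12) return(k)
    }
  }
  mov <- rep(NA_real_, length(h) - r + 1)
  for (k in seq_along(mov)) mov[k] <- sum(h[k:(k + r - 1)])
  c(
    Mean = m, Variance = v, Skewness = skew, Kurtosis = kurt,
    Perc01 = perc(0.01), Perc10 = perc(0.10), Perc50 = perc(0.50),
    Perc90 = perc(0.90), Perc99 = perc(0.99),
    Domn01 = ks[which(h == max(h))[1]],
    Domn10 = which(mov == max(mov))[1] - 1,
    Maxm01 = max(h), Maxm10 = max(mov)
  )
}

# Enumerate scan lines by walking from every line start in the step direction,
# then count maximal runs with an explicit state machine. NA / masked-out
# pixels terminate runs.
oracle_glrlm_matrix <- function(plane, mask = NULL, direction = 0, bits = 8) {
  nr <- nrow(plane)
  nc <- ncol(plane)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  member <- function(r, c) is.null(mask) || mask$membership[r, c]
  step <- switch(as.character(direction),
    "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0), "135" = c(-1, -1)
  )
  starts <- list()
  for (r in 1:nr) {
    for (c in 1:nc) {
      pr <- r - step[1]
      pc <- c - step[2]
      if (!inside(pr, pc)) starts[[length(starts) + 1]] <- c(r, c)
    }
  }
  p <- matrix(0, nrow = 2^bits, ncol = max(nr, nc))
  for (s in starts) {
    r <- s[1]
    c <- s[2]
    cur_level <- NA
    cur_len <- 0
    flush <- function() {
      if (cur_len > 0) p[cur_level + 1, cur_len] <<- p[cur_level + 1, cur_len] + 1
    }
    while (inside(r, c)) {
      if (!member(r, c)) {
        flush()
        cur_level <- NA
        cur_len <- 0
      } else if (!is.na(cur_level) && plane[r, c] == cur_level) {
        cur_len <- cur_len + 1
      } else {
        flush()
        cur_level <- plane[r, c]
        cur_len <- 1
      }
      r <- r + step[1]
      c <- c + step[2]
    }
    flush()
  }
  p
}

oracle_glrlm_features <- function(p) {
  np <- sum(p)
  gln <- rln <- lre <- sre <- 0
  npix <- 0
  for (i in seq_len(nrow(p))) gln <- gln + sum(p[i, ])^2
  for (j in seq_len(ncol(p))) {
    cs <- sum(p[, j])
    rln <- rln + cs^2
    lre <- lre + j^2 * cs
    sre <- sre + cs / j^2
    npix <- npix + j * cs
  }
  c(
    GLN = gln / np, RLN = rln / np, LRE = lre / np, SRE = sre / np,
    Fraction = np / npix, MRLN = rln / np^2, MGLN = gln / np^2
  )
}

# Pair enumeration over every pixel: symmetric accumulation, then optional
# normalization.
oracle_glcm_matrix <- function(plane, mask = NULL, d = 1, direction = 0,
                               bits = 8, normalize = TRUE) {
  nr <- nrow(plane)
  nc <- ncol(plane)
  off <- switch(as.character(direction),
    "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d)
  )
  member <- function(r, c) is.null(mask) || mask$membership[r, c]
  p <- matrix(0, 2^bits, 2^bits)
  for (r in 1:nr) {
    for (c in 1:nc) {
      r2 <- r + off[1]
      c2 <- c + off[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!member(r, c) || !member(r2, c2)) next
      a <- plane[r, c]
      b <- plane[r2, c2]
      p[a + 1, b + 1] <- p[a + 1, b + 1] + 1
      p[b + 1, a + 1] <- p[b + 1, a + 1] + 1
    }
  }
  if (normalize) p <- p / sum(p)
  p
}

oracle_glcm_features <- function(p, log_base = 2) {
  k <- nrow(p)
  lg <- function(x) log(x, base = log_base)
  asm <- contrast <- idm <- entropy <- 0
  mu_i <- mu_j <- 0
  for (i in 1:k) {
    for (j in 1:k) {
      pij <- p[i, j]
      gi <- i - 1
      gj <- j - 1
      asm <- asm + pij^2
      contrast <- contrast + (gi - gj)^2 * pij
      idm <- idm + pij / (1 + (gi - gj)^2)
      if (pij > 0) entropy <- entropy - pij * lg(pij)
      mu_i <- mu_i + gi * pij
      mu_j <- mu_j + gj * pij
    }
  }
  var_i <- var_j <- cross <- sumsq <- 0
  for (i in 1:k) {
    for (j in 1:k) {
      pij <- p[i, j]
      gi <- i - 1
      gj <- j - 1
      var_i <- var_i + (gi - mu_i)^2 * pij
      var_j <- var_j + (gj - mu_j)^2 * pij
      cross <- cross + gi * gj * pij
      sumsq <- sumsq + (gi - mu_i)^2 * pij
    }
  }
  correlat <- if (var_i > 0 && var_j > 0) {
    (cross - mu_i * mu_j) / (sqrt(var_i) * sqrt(var_j))
  } else {
    0
  }
  p_sum <- numeric(2 * k - 1) # index s+1 holds P(i+j = s), s in 0..2k-2
  p_dif <- numeric(k)         # index t+1 holds P(|i-j| = t)
  for (i in 1:k) {
    for (j in 1:k) {
      p_sum[(i - 1) + (j - 1) + 1] <- p_sum[(i - 1) + (j - 1) + 1] + p[i, j]
      p_dif[abs(i - j) + 1] <- p_dif[abs(i - j) + 1] + p[i, j]
    }
  }
  sum_avg <- sum((seq_along(p_sum) - 1) * p_sum)
  sum_var <- sum((seq_along(p_sum) - 1 - sum_avg)^2 * p_sum)
  sum_ent <- -sum(p_sum[p_sum > 0] * lg(p_sum[p_sum > 0]))
  dif_mu <- sum((seq_along(p_dif) - 1) * p_dif)
  dif_var <- sum((seq_along(p_dif) - 1 - dif_mu)^2 * p_dif)
  dif_ent <- -sum(p_dif[p_dif > 0] * lg(p_dif[p_dif > 0]))
  c(
    AngScMom = asm, Contrast = contrast, Correlat = correlat,
    SumOfSqs = sumsq, InvDefMom = idm, SumAverg = sum_avg,
    SumVarnc = sum_var, SumEntrp = sum_ent, Entropy = entropy,
    DifVarnc = dif_var, DifEntrp = dif_ent
  )
}

# All 31 features by the oracle route, mirroring texture_config averaging.
oracle_texture_features <- function(plane, mask = NULL, config = texture_config()) {
  values <- if (is.null(mask)) as.vector(plane) else plane[mask$membership]
  hs <- oracle_hs(values, config$bits, config$window)
  glrlm <- rowMeans(sapply(config$glrlm_directions, function(dir) {
    oracle_glrlm_features(oracle_glrlm_matrix(plane, mask, dir, config$bits))
  }))
  glcm <- rowMeans(sapply(config$glcm_directions, function(dir) {
    oracle_glcm_features(
      oracle_glcm_matrix(plane, mask, config$d, dir, config$bits),
      config$log_base
    )
  }))
  c(hs, glrlm, glcm)
}

random_plane <- function(seed, nr = NULL, nc = NULL, bits = 8) {
  set.seed(seed)
  if (is.null(nr)) nr <- sample(8:16, 1)
  if (is.null(nc)) nc <- sample(8:16, 1)
  matrix(sample(0:(2^bits - 1), nr * nc, replace = TRUE), nr, nc)
}
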