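# Brute-force texture oracles: naive loop implementations of the gray-level
# matrices and their features, written directly from the definitions and kept
# independent of the package's vectorised builders.

o_neighbour_offsets <- function(ndim) {
  if (ndim == 2) {
    o <- expand.grid(dx = -1:1, dy = -1:1)
    o <- o[!(o$dx == 0 & o$dy == 0), ]
    cbind(o$dx, o$dy)
  } else {
    o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    o <- o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ]
    cbind(o$dx, o$dy, o$dz)
  }
}

o_half_offsets <- function(ndim) {
  offs <- o_neighbour_offsets(ndim)
  keep <- logical(nrow(offs))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nz <- which(o != 0)
    keep[r] <- o[nz[length(nz)]] > 0
  }
  offs[keep, , drop = FALSE]
}

o_coords <- function(dm) as.matrix(expand.grid(lapply(dm, seq_len)))

o_get <- function(lev, cc) {
  if (any(cc < 1) || any(cc > dim(lev))) return(NA_integer_)
  if (length(cc) == 2) lev[cc[1], cc[2]] else lev[cc[1], cc[2], cc[3]]
}

# symmetric normalised GLCM for one offset, counting both directions
o_glcm <- function(lev, ng, off) {
  dm <- dim(lev)
  m <- matrix(0, ng, ng)
  for (r in seq_len(nrow(cc <- o_coords(dm)))) {
    a <- o_get(lev, cc[r, ])
    if (is.na(a)) next
    for (s in c(1, -1)) {
      b <- o_get(lev, cc[r, ] + s * off)
      if (!is.na(b)) m[a, b] <- m[a, b] + 1
    }
  }
  if (sum(m) == 0) return(NULL)
  m / sum(m)
}

# run-length matrix for one direction by walking each run start
o_glrlm <- function(lev, ng, off) {
  dm <- dim(lev)
  cc <- o_coords(dm)
  runs <- list()
  for (r in seq_len(nrow(cc))) {
    a <- o_get(lev, cc[r, ])
    if (is.na(a)) next
    prev <- o_get(lev, cc[r, ] - off)
    if (!is.na(prev) && prev == a) next  # not a run start
    len <- 1
    pos <- cc[r, ] + off
    while (!is.na(b <- o_get(lev, pos)) && b == a) {
      len <- len + 1
      pos <- pos + off
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  if (length(runs) == 0) return(NULL)
  rl <- do.call(rbind, runs)
  m <- matrix(0, ng, max(rl[, 2]))
  for (r in seq_len(nrow(rl))) m[rl[r, 1], rl[r, 2]] <- m[rl[r, 1], rl[r, 2]] + 1
  m
}

# size-zone matrix via recursive flood fill over the full neighbourhood
o_glszm <- function(lev, ng) {
  dm <- dim(lev)
  offs <- o_neighbour_offsets(length(dm))
  seen <- array(FALSE, dm)
  cc <- o_coords(dm)
  key <- function(p) paste(p, collapse = ",")
  idx <- function(p) if (length(p) == 2) seen[p[1], p[2]] else seen[p[1], p[2], p[3]]
  setidx <- function(p) {
    if (length(p) == 2) seen[p[1], p[2]] <<- TRUE else seen[p[1], p[2], p[3]] <<- TRUE
  }
  zones <- list()
  for (r in seq_len(nrow(cc))) {
    a <- o_get(lev, cc[r, ])
    if (is.na(a) || idx(cc[r, ])) next
    size <- 0
    queue <- list(cc[r, ])
    setidx(cc[r, ])
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        b <- o_get(lev, q)
        if (!is.na(b) && b == a && !idx(q)) {
          setidx(q)
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  zl <- do.call(rbind, zones)
  m <- matrix(0, ng, max(zl[, 2]))
  for (r in seq_len(nrow(zl))) m[zl[r, 1], zl[r, 2]] <- m[zl[r, 1], zl[r, 2]] + 1
  m
}

# dependence matrix: columns are dependence size = equal neighbours + 1
o_gldm <- function(lev, ng) {
  dm <- dim(lev)
  offs <- o_neighbour_offsets(length(dm))
  cc <- o_coords(dm)
  recs <- list()
  for (r in seq_len(nrow(cc))) {
    a <- o_get(lev, cc[r, ])
    if (is.na(a)) next
    d <- 0
    for (k in seq_len(nrow(offs))) {
      b <- o_get(lev, cc[r, ] + offs[k, ])
      if (!is.na(b) && b == a) d <- d + 1
    }
    recs[[length(recs) + 1]] <- c(a, d + 1)
  }
  rl <- do.call(rbind, recs)
  m <- matrix(0, ng, max(rl[, 2]))
  for (r in seq_len(nrow(rl))) m[rl[r, 1], rl[r, 2]] <- m[rl[r, 1], rl[r, 2]] + 1
  m
}

o_ngtdm <- function(lev, ng) {
  dm <- dim(lev)
  offs <- o_neighbour_offsets(length(dm))
  cc <- o_coords(dm)
  n_i <- numeric(ng); s_i <- numeric(ng); nvp <- 0
  for (r in seq_len(nrow(cc))) {
    a <- o_get(lev, cc[r, ])
    if (is.na(a)) next
    nb <- c()
    for (k in seq_len(nrow(offs))) {
      b <- o_get(lev, cc[r, ] + offs[k, ])
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    nvp <- nvp + 1
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  list(n = n_i, s = s_i, nvp = nvp)
}

# --- feature formulas from the definitions (plain loops) -------------------

o_glcm_features <- function(p) {
  ng <- nrow(p)
  eps <- 2.2e-16
  px <- rowSums(p)
  mu <- 0; for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  s2 <- 0; for (i in 1:ng) for (j in 1:ng) s2 <- s2 + (i - mu)^2 * p[i, j]
  psum <- numeric(2 * ng); pdif <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  f <- c(
    Autocorrelation = sum(outer(1:ng, 1:ng) * p),
    JointAverage = mu,
    ClusterProminence = sum(outer(1:ng, 1:ng, function(i, j) (i + j - 2 * mu)^4) * p),
    ClusterShade = sum(outer(1:ng, 1:ng, function(i, j) (i + j - 2 * mu)^3) * p),
    ClusterTendency = sum(outer(1:ng, 1:ng, function(i, j) (i + j - 2 * mu)^2) * p),
    Contrast = sum(outer(1:ng, 1:ng, function(i, j) (i - j)^2) * p),
    Correlation = if (s2 > 0)
      (sum(outer(1:ng, 1:ng) * p) - mu^2) / s2 else 1,
    DifferenceAverage = sum((0:(ng - 1)) * pdif),
    DifferenceEntropy = -sum(pdif * log2(pdif + eps)),
    DifferenceVariance = sum(((0:(ng - 1)) - sum((0:(ng - 1)) * pdif))^2 * pdif),
    JointEnergy = sum(p^2),
    JointEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    Imc1 = NA, Imc2 = NA,
    Idm = sum(p / (1 + outer(1:ng, 1:ng, function(i, j) (i - j)^2))),
    Idmn = sum(p / (1 + outer(1:ng, 1:ng, function(i, j) ((i - j) / ng)^2))),
    Id = sum(p / (1 + abs(outer(1:ng, 1:ng, "-")))),
    Idn = sum(p / (1 + abs(outer(1:ng, 1:ng, "-")) / ng)),
    InverseVariance = {
      v <- 0
      for (i in 1:ng) for (j in 1:ng) if (i != j) v <- v + p[i, j] / (i - j)^2
      v
    },
    MaximumProbability = max(p),
    SumEntropy = -sum(psum[psum > 0] * log2(psum[psum > 0] + eps)),
    SumSquares = s2
  )
  hx <- -sum(px * log2(px + eps))
  hxy <- -sum(p[p > 0] * log2(p[p > 0]))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    hxy1 <- hxy1 - p[i, j] * log2(px[i] * px[j] + eps)
    hxy2 <- hxy2 - px[i] * px[j] * log2(px[i] * px[j] + eps)
  }
  f["Imc1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  f["Imc2"] <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  names(f) <- paste0("glcm_", names(f))
  f
}

# emphasis-style features shared by GLRLM / GLSZM / GLDM oracles
o_rl_features <- function(m, np) {
  ng <- nrow(m); L <- ncol(m)
  nr <- sum(m)
  pm <- m / nr
  eps <- 2.2e-16
  mug <- 0; mus <- 0
  for (g in 1:ng) for (s in 1:L) { mug <- mug + g * pm[g, s]; mus <- mus + s * pm[g, s] }
  acc <- function(f) {
    v <- 0
    for (g in 1:ng) for (s in 1:L) v <- v + f(g, s) * m[g, s]
    v / nr
  }
  c(se = acc(function(g, s) 1 / s^2),
    le = acc(function(g, s) s^2),
    gln = sum(rowSums(m)^2) / nr,
    glnn = sum(rowSums(m)^2) / nr^2,
    sn = sum(colSums(m)^2) / nr,
    snn = sum(colSums(m)^2) / nr^2,
    perc = nr / np,
    glv = acc(function(g, s) (g - mug)^2) / 1,
    sv = acc(function(g, s) (s - mus)^2) / 1,
    ent = -sum(pm[pm > 0] * log2(pm[pm > 0] + eps)),
    lgle = acc(function(g, s) 1 / g^2),
    hgle = acc(function(g, s) g^2),
    slgle = acc(function(g, s) 1 / (g^2 * s^2)),
    shgle = acc(function(g, s) g^2 / s^2),
    llgle = acc(function(g, s) s^2 / g^2),
    lhgle = acc(function(g, s) g^2 * s^2))
}

o_ngtdm_features <- function(tb) {
  n <- tb$n; s <- tb$s; nvp <- tb$nvp
  out <- c(Coarseness = 1e6, Contrast = 0, Busyness = 0, Complexity = 0,
           Strength = 0)
  if (nvp == 0) { names(out) <- paste0("ngtdm_", names(out)); return(out) }
  p <- n / nvp
  act <- which(p > 0); ngp <- length(act)
  den <- sum(p * s)
  if (den > 0) out["Coarseness"] <- min(1 / den, 1e6)
  if (ngp > 1) {
    con <- 0; busy_den <- 0; comp <- 0; str_num <- 0
    for (i in act) for (j in act) {
      con <- con + p[i] * p[j] * (i - j)^2
      busy_den <- busy_den + abs(i * p[i] - j * p[j])
      comp <- comp + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
      str_num <- str_num + (p[i] + p[j]) * (i - j)^2
    }
    out["Contrast"] <- con / (ngp * (ngp - 1)) * sum(s) / nvp
    if (busy_den > 0) out["Busyness"] <- den / busy_den
    out["Complexity"] <- comp / nvp
    if (sum(s) > 0) out["Strength"] <- str_num / sum(s)
  }
  names(out) <- paste0("ngtdm_", names(out))
  out
}

# full oracle feature vector for one texture class on a discretized image
o_texture_features <- function(lev, ng, class, np) {
  ndim <- length(dim(lev))
  switch(class,
    glcm = {
      offs <- o_half_offsets(ndim)
      mats <- list()
      for (r in seq_len(nrow(offs))) {
        m <- o_glcm(lev, ng, offs[r, ])
        if (!is.null(m)) mats[[length(mats) + 1]] <- m
      }
      if (length(mats) == 0) mats <- list(matrix(1, 1, 1))
      Reduce(`+`, lapply(mats, o_glcm_features)) / length(mats)
    },
    glrlm = {
      offs <- o_half_offsets(ndim)
      fs <- list()
      for (r in seq_len(nrow(offs))) {
        m <- o_glrlm(lev, ng, offs[r, ])
        if (!is.null(m)) fs[[length(fs) + 1]] <- o_rl_features(m, np)
      }
      v <- Reduce(`+`, fs) / length(fs)
      names(v) <- paste0("glrlm_", radiopathomics:::rp_glrlm_names)
      v
    },
    glszm = {
      v <- o_rl_features(o_glszm(lev, ng), np)
      names(v) <- paste0("glszm_", radiopathomics:::rp_glszm_names)
      v
    },
    gldm = {
      v <- o_rl_features(o_gldm(lev, ng), np)
      v <- v[c("se", "le", "gln", "sn", "snn", "glv", "sv", "ent",
               "lgle", "hgle", "slgle", "shgle", "llgle", "lhgle")]
      names(v) <- paste0("gldm_", radiopathomics:::rp_gldm_names)
      v
    },
    ngtdm = o_ngtdm_features(o_ngtdm(lev, ng))
  )
}

# random small test instance (2D or 3D) with Ng <= max_ng
random_instance <- function(ndim, max_side = 5, max_ng = 4) {
  dm <- if (ndim == 2) c(sample(2:max_side, 1), sample(2:max_side, 1))
    else c(sample(2:4, 1), sample(2:4, 1), sample(2:3, 1))
  img <- array(sample(seq_len(max_ng), prod(dm), replace = TRUE), dm)
  mask <- array(runif(prod(dm)) < 0.85, dm)
  if (!any(mask)) mask[1] <- TRUE
  list(image = img * 1.0, mask = mask)
}
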