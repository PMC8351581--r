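# Naive brute-force descriptor oracles: explicit loops over windows,
# pairs and lags, counting with string keys in hashed environments.
# They share only the published constant tables with the package.

o_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

o_count <- function(env, key) {
  v <- env[[key]]
  if (is.null(v)) 0 else v
}

o_bump <- function(env, key) {
  env[[key]] <- o_count(env, key) + 1
}

o_group_of <- function(ch, groups) {
  for (g in names(groups)) if (ch %in% groups[[g]]) return(g)
  stop("ungrouped residue ", ch)
}

oracle_tpc <- function(s) {
  ch <- o_chars(s); n <- length(ch)
  e <- new.env(hash = TRUE)
  for (i in 1:(n - 2)) o_bump(e, paste0(ch[i], ch[i + 1], ch[i + 2]))
  out <- numeric(8000); pos <- 0
  for (r in AA20) for (s2 in AA20) for (t in AA20) {
    pos <- pos + 1
    out[pos] <- o_count(e, paste0(r, s2, t))
  }
  out / (n - 2)
}

oracle_gtpc <- function(s) {
  groups <- pmpred:::AA_GROUPS5
  ch <- vapply(o_chars(s), o_group_of, character(1), groups = groups)
  n <- length(ch)
  e <- new.env(hash = TRUE)
  for (i in 1:(n - 2)) o_bump(e, paste(ch[i], ch[i + 1], ch[i + 2], sep = "."))
  out <- numeric(125); pos <- 0
  for (a in names(groups)) for (b in names(groups)) for (d in names(groups)) {
    pos <- pos + 1
    out[pos] <- o_count(e, paste(a, b, d, sep = "."))
  }
  out / (n - 2)
}

oracle_cksaap <- function(s, k_max) {
  ch <- o_chars(s); n <- length(ch)
  out <- numeric(0)
  for (k in 0:k_max) {
    e <- new.env(hash = TRUE)
    for (i in 1:(n - k - 1)) o_bump(e, paste0(ch[i], ch[i + k + 1]))
    block <- numeric(400); pos <- 0
    for (a in AA20) for (b in AA20) {
      pos <- pos + 1
      block[pos] <- o_count(e, paste0(a, b))
    }
    out <- c(out, block / (n - k - 1))
  }
  out
}

oracle_cksaagp <- function(s, k_max) {
  groups <- pmpred:::AA_GROUPS5
  ch <- vapply(o_chars(s), o_group_of, character(1), groups = groups)
  n <- length(ch)
  out <- numeric(0)
  for (k in 0:k_max) {
    e <- new.env(hash = TRUE)
    for (i in 1:(n - k - 1)) o_bump(e, paste(ch[i], ch[i + k + 1], sep = "."))
    block <- numeric(25); pos <- 0
    for (a in names(groups)) for (b in names(groups)) {
      pos <- pos + 1
      block[pos] <- o_count(e, paste(a, b, sep = "."))
    }
    out <- c(out, block / (n - k - 1))
  }
  out
}

oracle_ksctriad <- function(s, k_max) {
  groups <- pmpred:::AA_CONJOINT7
  ch <- vapply(o_chars(s), o_group_of, character(1), groups = groups)
  n <- length(ch)
  out <- numeric(0)
  for (k in 0:k_max) {
    e <- new.env(hash = TRUE)
    m <- n - 2 * k - 2
    for (i in 1:m) {
      o_bump(e, paste(ch[i], ch[i + k + 1], ch[i + 2 * k + 2], sep = "."))
    }
    block <- numeric(343); pos <- 0
    for (a in names(groups)) for (b in names(groups)) for (d in names(groups)) {
      pos <- pos + 1
      block[pos] <- o_count(e, paste(a, b, d, sep = "."))
    }
    out <- c(out, block / m)
  }
  out
}

oracle_dde <- function(s) {
  ch <- o_chars(s); n <- length(ch)
  cod <- pmpred:::AA_CODON_COUNTS
  e <- new.env(hash = TRUE)
  for (i in 1:(n - 1)) o_bump(e, paste0(ch[i], ch[i + 1]))
  out <- numeric(400); pos <- 0
  for (r in AA20) for (s2 in AA20) {
    dc <- o_count(e, paste0(r, s2)) / (n - 1)
    tm <- (cod[[r]] / 61) * (cod[[s2]] / 61)
    tv <- tm * (1 - tm) / (n - 1)
    pos <- pos + 1
    out[pos] <- (dc - tm) / sqrt(tv)
  }
  out
}

oracle_ctdc <- function(s) {
  ch <- o_chars(s); n <- length(ch)
  out <- numeric(0)
  for (prop in pmpred:::CTD_PROPERTIES) {
    for (g in prop) {
      cnt <- 0
      for (c0 in ch) if (c0 %in% g) cnt <- cnt + 1
      out <- c(out, cnt / n)
    }
  }
  out
}

oracle_ctdt <- function(s) {
  ch <- o_chars(s); n <- length(ch)
  out <- numeric(0)
  for (prop in pmpred:::CTD_PROPERTIES) {
    g <- vapply(ch, o_group_of, character(1), groups = prop)
    for (pair in list(c("g1", "g2"), c("g1", "g3"), c("g2", "g3"))) {
      cnt <- 0
      for (i in 1:(n - 1)) {
        if ((g[i] == pair[1] && g[i + 1] == pair[2]) ||
            (g[i] == pair[2] && g[i + 1] == pair[1])) cnt <- cnt + 1
      }
      out <- c(out, cnt / (n - 1))
    }
  }
  out
}

oracle_ctdd <- function(s) {
  ch <- o_chars(s); n <- length(ch)
  out <- numeric(0)
  for (prop in pmpred:::CTD_PROPERTIES) {
    for (g in prop) {
      pos <- c()
      for (i in 1:n) if (ch[i] %in% g) pos <- c(pos, i)
      if (!length(pos)) {
        out <- c(out, rep(0, 5))
      } else {
        ng <- length(pos)
        for (q in c(0, 0.25, 0.5, 0.75, 1)) {
          r <- if (q == 0) 1 else if (q == 1) ng else
            min(max(ceiling(q * ng), 1), ng)
          out <- c(out, 100 * pos[r] / n)
        }
      }
    }
  }
  out
}

o_zscale <- function(x) {
  m <- sum(x) / length(x)
  s2 <- 0
  for (v in x) s2 <- s2 + (v - m)^2
  (x - m) / sqrt(s2 / length(x))
}

oracle_autocorr <- function(s, nlag, kind) {
  ch <- o_chars(s); n <- length(ch)
  props <- pmpred:::AA_AUTOCORR_PROPS
  out <- numeric(0)
  for (p in seq_len(nrow(props))) {
    z <- o_zscale(props[p, ])
    x <- numeric(n)
    for (i in 1:n) x[i] <- z[[ch[i]]]
    xbar <- sum(x) / n
    ss <- 0
    for (v in x) ss <- ss + (v - xbar)^2
    for (d in 1:nlag) {
      num <- 0
      if (kind == "moran") {
        for (i in 1:(n - d)) num <- num + (x[i] - xbar) * (x[i + d] - xbar)
        out <- c(out, if (ss == 0) 0 else (num / (n - d)) / (ss / n))
      } else if (kind == "geary") {
        for (i in 1:(n - d)) num <- num + (x[i] - x[i + d])^2
        out <- c(out, if (ss == 0) 0 else
          (num / (2 * (n - d))) / (ss / (n - 1)))
      } else {
        for (i in 1:(n - d)) num <- num + x[i] * x[i + d]
        out <- c(out, num / (n - d))
      }
    }
  }
  out
}

o_taus <- function(ch, nlag, dm) {
  n <- length(ch)
  tau <- numeric(nlag)
  for (d in 1:nlag) {
    for (i in 1:(n - d)) tau[d] <- tau[d] + dm[ch[i], ch[i + d]]^2
  }
  tau
}

oracle_socnumber <- function(s, nlag) {
  ch <- o_chars(s)
  c(o_taus(ch, nlag, pmpred:::pcd_distance_matrix()),
    o_taus(ch, nlag, pmpred:::grantham_distance_matrix()))
}

oracle_qsorder <- function(s, nlag, w) {
  ch <- o_chars(s); n <- length(ch)
  tp <- o_taus(ch, nlag, pmpred:::pcd_distance_matrix())
  tg <- o_taus(ch, nlag, pmpred:::grantham_distance_matrix())
  f <- numeric(20); names(f) <- AA20
  for (c0 in ch) f[c0] <- f[c0] + 1
  c(f / (n + w * sum(tp)), f / (n + w * sum(tg)),
    w * tp / (n + w * sum(tp)), w * tg / (n + w * sum(tg)))
}

oracle_paac <- function(s, lambda, w) {
  ch <- o_chars(s); n <- length(ch)
  props <- pmpred:::AA_PAAC_PROPS
  z <- t(apply(props, 1, o_zscale))
  theta <- numeric(lambda)
  for (d in 1:lambda) {
    acc <- 0
    for (i in 1:(n - d)) {
      acc <- acc + ((z[1, ch[i]] - z[1, ch[i + d]])^2 +
                    (z[2, ch[i]] - z[2, ch[i + d]])^2 +
                    (z[3, ch[i]] - z[3, ch[i + d]])^2) / 3
    }
    theta[d] <- acc / (n - d)
  }
  f <- numeric(20); names(f) <- AA20
  for (c0 in ch) f[c0] <- f[c0] + 1
  den <- 1 + w * sum(theta)
  c((f / n) / den, w * theta / den)
}

oracle_apaac <- function(s, lambda, w) {
  ch <- o_chars(s); n <- length(ch)
  z <- t(apply(pmpred:::AA_PAAC_PROPS, 1, o_zscale))
  tau <- numeric(2 * lambda)
  for (d in 1:lambda) {
    for (p in 1:2) {
      acc <- 0
      for (i in 1:(n - d)) acc <- acc + z[p, ch[i]] * z[p, ch[i + d]]
      tau[2 * (d - 1) + p] <- acc / (n - d)
    }
  }
  f <- numeric(20); names(f) <- AA20
  for (c0 in ch) f[c0] <- f[c0] + 1
  den <- 1 + w * sum(tau)
  c((f / n) / den, w * tau / den)
}

oracle_descriptor <- function(s, spec) {
  p <- spec$params
  switch(spec$class_name,
    TPC = oracle_tpc(s),
    GTPC = oracle_gtpc(s),
    CKSAAP = oracle_cksaap(s, p$k_max),
    CKSAAGP = oracle_cksaagp(s, p$k_max),
    KSCTriad = oracle_ksctriad(s, p$k_max),
    DDE = oracle_dde(s),
    CTDC = oracle_ctdc(s),
    CTDT = oracle_ctdt(s),
    CTDD = oracle_ctdd(s),
    Moran = oracle_autocorr(s, p$nlag, "moran"),
    Geary = oracle_autocorr(s, p$nlag, "geary"),
    NMBroto = oracle_autocorr(s, p$nlag, "nmbroto"),
    SOCNumber = oracle_socnumber(s, p$nlag),
    QSOrder = oracle_qsorder(s, p$nlag, p$weight),
    PAAC = oracle_paac(s, p$lambda, p$weight),
    APAAC = oracle_apaac(s, p$lambda, p$weight))
}

# Brute-force ranking-metric oracles for small instances.
oracle_auc_pairs <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  acc <- 0
  for (i in pos) for (j in neg) {
    acc <- acc + if (scores[i] > scores[j]) 1 else
      if (scores[i] == scores[j]) 0.5 else 0
  }
  acc / (length(pos) * length(neg))
}

oracle_auprc_enum <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  prev_rec <- 0; area <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    prec <- tp / (tp + fp)
    rec <- tp / n1
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

oracle_auc_trapezoid <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tpr[i] <- sum(pred & labels == 1) / n1
    fpr[i] <- sum(pred & labels == 0) / n0
  }
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}
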