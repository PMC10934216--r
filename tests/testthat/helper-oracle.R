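# Brute-force SSR mining oracle, independent of the package's rle-based
# period scan. Every (position, motif length 1-6) pair is tested by direct
# substring comparison; overlapping maximal runs are resolved by
# exhaustively enumerating all segmentations of the overlap cluster's span
# and picking the optimum under the documented policy (fewest components,
# then longest first component, then lowest class).

oracle_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in 1:(k - 1L)) {
    if (k %% d == 0L &&
        paste(rep(substr(motif, 1L, d), k / d), collapse = "") == motif) {
      return(FALSE)
    }
  }
  TRUE
}

# all maximal qualifying runs, brute force
oracle_candidates <- function(chars, thr) {
  n <- length(chars)
  out <- list()
  for (i in seq_len(n)) {
    if (chars[i] == "N") next
    for (k in 1:6) {
      if (i + 2L * k - 1L > n) next
      motif <- chars[i:(i + k - 1L)]
      if (any(motif == "N")) next
      mstr <- paste(motif, collapse = "")
      if (!oracle_primitive(mstr)) next
      # full copies by direct comparison
      m <- 1L
      repeat {
        a <- i + m * k; b <- i + (m + 1L) * k - 1L
        if (b > n || !all(chars[a:b] == motif)) break
        m <- m + 1L
      }
      if (m < thr[[k]]) next
      # run start: the character-level period must not extend left
      if (i > 1L && chars[i - 1L] != "N" &&
          chars[i - 1L] == chars[i + k - 1L]) next
      e <- i + m * k - 1L
      ext <- e
      while (ext + 1L <= n && chars[ext + 1L] != "N" &&
             chars[ext + 1L] == chars[ext + 1L - k]) ext <- ext + 1L
      out[[length(out) + 1L]] <- data.frame(
        start = i, end = e, ext_end = ext, class = k, repeats = m,
        motif = mstr, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  cand <- do.call(rbind, out)
  cand <- cand[order(cand$start, cand$end, cand$class), , drop = FALSE]
  cand[!duplicated(cand[, c("start", "end")]), , drop = FALSE]
}

# every way to tile chars completely with qualifying perfect runs
oracle_covers <- function(chars, thr) {
  n <- length(chars)
  res <- list()
  rec <- function(i, acc) {
    if (i > n) {
      res[[length(res) + 1L]] <<- acc
      return()
    }
    for (k in 1:6) {
      if (i + 2L * k - 1L > n) next
      motif <- chars[i:(i + k - 1L)]
      if (any(motif == "N")) next
      if (!oracle_primitive(paste(motif, collapse = ""))) next
      m <- 1L
      repeat {
        a <- i + m * k; b <- i + (m + 1L) * k - 1L
        if (b > n || !all(chars[a:b] == motif)) break
        m <- m + 1L
      }
      if (m < thr[[k]]) next
      for (r in thr[[k]]:m) {
        rec(i + r * k, rbind(acc, data.frame(
          start = i, end = i + r * k - 1L, class = k, repeats = r,
          motif = paste(motif, collapse = ""), stringsAsFactors = FALSE)))
      }
    }
  }
  rec(1L, NULL)
  res
}

# policy order: fewest components, longest first component (then second,
# ...), lowest class on remaining ties
oracle_best_cover <- function(covers) {
  if (length(covers) == 0L) return(NULL)
  score <- function(cv) {
    lens <- cv$end - cv$start + 1L
    # lexicographic: fewer rows, then longer components left to right,
    # then smaller classes
    list(nrow(cv), lens, cv$class)
  }
  best <- covers[[1L]]
  for (cv in covers[-1L]) {
    a <- score(cv); b <- score(best)
    if (a[[1L]] < b[[1L]]) { best <- cv; next }
    if (a[[1L]] > b[[1L]]) next
    cmp <- 0L
    for (j in seq_along(a[[2L]])) {
      if (a[[2L]][j] != b[[2L]][j]) { cmp <- sign(a[[2L]][j] - b[[2L]][j]); break }
    }
    if (cmp == 1L) { best <- cv; next }
    if (cmp == -1L) next
    for (j in seq_along(a[[3L]])) {
      if (a[[3L]][j] != b[[3L]][j]) { cmp <- sign(b[[3L]][j] - a[[3L]][j]); break }
    }
    if (cmp == 1L) best <- cv
  }
  best
}

oracle_mine <- function(s, thr = default_thresholds()) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  cand <- oracle_candidates(chars, thr)
  empty <- data.frame(start = integer(0), end = integer(0),
                      class = integer(0), repeats = integer(0),
                      motif = character(0), stringsAsFactors = FALSE)
  if (is.null(cand)) return(empty)
  # transitive overlap clusters on complete-copy intervals
  cl <- integer(nrow(cand)); cur <- 0L; cur_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > cur_end) cur <- cur + 1L
    cl[i] <- cur
    cur_end <- max(cur_end, cand$end[i])
  }
  picked <- list()
  for (g in split(seq_len(nrow(cand)), cl)) {
    if (length(g) == 1L) {
      picked[[length(picked) + 1L]] <-
        cand[g, c("start", "end", "class", "repeats", "motif")]
      next
    }
    sub <- cand[g, , drop = FALSE]
    a <- min(sub$start)
    seg <- NULL
    for (b in unique(c(max(sub$ext_end), max(sub$end)))) {
      covers <- oracle_covers(chars[a:b], thr)
      if (length(covers) > 0L) { seg <- oracle_best_cover(covers); break }
    }
    if (!is.null(seg)) {
      seg$start <- seg$start + a - 1L
      seg$end <- seg$end + a - 1L
      picked[[length(picked) + 1L]] <- seg
    } else {
      sub <- sub[order(-(sub$end - sub$start + 1L), sub$class, sub$start), ,
                 drop = FALSE]
      ts <- integer(0); te <- integer(0)
      for (i in seq_len(nrow(sub))) {
        if (!any(sub$start[i] <= te & sub$end[i] >= ts)) {
          ts <- c(ts, sub$start[i]); te <- c(te, sub$end[i])
          picked[[length(picked) + 1L]] <-
            sub[i, c("start", "end", "class", "repeats", "motif")]
        }
      }
    }
  }
  out <- do.call(rbind, picked)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random test sequences: background plus occasional planted repeat runs,
# adjacent pairs and rare Ns, to exercise thresholds, compounding,
# overlaps and run breaking
random_test_seq <- function(len) {
  bases <- c("A", "C", "G", "T")
  x <- sample(bases, len, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
  s <- paste(x, collapse = "")
  n_plant <- sample(0:3, 1L, prob = c(0.4, 0.3, 0.2, 0.1))
  for (j in seq_len(n_plant)) {
    k <- sample(1:6, 1L)
    motif <- random_primitive_motif(k)
    r <- sample(2:15, 1L)
    run <- strrep(motif, r)
    if (stats::runif(1L) < 0.3) {
      k2 <- sample(1:6, 1L)
      run <- paste0(run, strrep(random_primitive_motif(k2), sample(2:8, 1L)))
    }
    if (nchar(run) >= nchar(s)) next
    pos <- sample.int(nchar(s) - nchar(run), 1L)
    substr(s, pos, pos + nchar(run) - 1L) <- run
  }
  if (stats::runif(1L) < 0.15 && nchar(s) > 2L) {
    pos <- sample.int(nchar(s), 1L)
    substr(s, pos, pos) <- "N"
  }
  s
}

random_primitive_motif <- function(k) {
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
               collapse = "")
    if (is_primitive_motif(m)) return(m)
  }
}

expect_same_ssrs <- function(got, want, info = NULL) {
  sig <- function(df) paste(df$start, df$end, df$class, df$repeats,
                            df$motif, sep = ":", collapse = ";")
  expect_identical(sig(got), sig(want), info = info)
}
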