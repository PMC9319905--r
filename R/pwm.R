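#' Position weight matrix constructor
#'
#' @param id motif id; @param name RBP name (defaults to id).
#' @param mat 4 x L probability matrix, rows A, C, G, T (U is mapped to T
#'   on input); every column must sum to 1 (tolerance 1e-6); L >= 4.
#' @param bkg background nucleotide composition (named, A/C/G/T), default
#'   uniform.
#' @return object of class `pwm`.
#' @export
pwm <- function(id, mat, name = id,
                bkg = c(A = .25, C = .25, G = .25, T = .25)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
  if (ncol(mat) < 4L) stop("PWM length must be >= 4")
  if (any(abs(colSums(mat) - 1) > 1e-6)) {
    stop("PWM columns must sum to 1")
  }
  bkg <- bkg[c("A", "C", "G", "T")]
  if (anyNA(bkg) || abs(sum(bkg) - 1) > 1e-6) {
    stop("background must be a length-4 composition summing to 1")
  }
  structure(list(id = id, name = name, mat = mat, bkg = bkg),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), length %d, consensus %s\n", x$id, x$name,
              ncol(x$mat), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence (highest-probability base per position)
#' @param x a `pwm`.
#' @return character string.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$mat)[apply(x$mat, 2, which.max)], collapse = "")
}

#' Read motifs in MEME (minimal) format
#'
#' Supports the standard minimal MEME text format: `MOTIF id name` headers,
#' an optional `Background letter frequencies` line, and letter-probability
#' matrices. RNA alphabets (ACGU) are mapped to DNA.
#'
#' @param path file path.
#' @return list of `pwm` objects, named by motif id.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bkg <- c(A = .25, C = .25, G = .25, T = .25)
  bl <- grep("^Background letter frequencies", lines)
  if (length(bl)) {
    tok <- strsplit(trimws(lines[bl[1L] + 1L]), "\\s+")[[1L]]
    v <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(v) <- sub("U", "T", toupper(tok[seq(1, length(tok), by = 2)]))
    bkg <- v[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF", lines)
  out <- list()
  for (s in starts) {
    tok <- strsplit(trimws(lines[s]), "\\s+")[[1L]]
    id <- tok[2L]; name <- if (length(tok) >= 3L) tok[3L] else tok[2L]
    h <- s + which(grepl("^letter-probability matrix",
                         lines[(s + 1L):length(lines)]))[1L]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1L):(h + w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]][1:4])
    }, numeric(4)))
    out[[id]] <- pwm(id, t(mat), name = name, bkg = bkg)
  }
  out
}

#' Write motifs in MEME (minimal) format
#' @param pwms list of `pwm` objects. @param path output file.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "", "Background letter frequencies"), con)
  bkg <- pwms[[1L]]$bkg
  writeLines(paste(sprintf("%s %.5f", names(bkg), bkg), collapse = " "), con)
  for (p in pwms) {
    writeLines(c("", sprintf("MOTIF %s %s", p$id, p$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         ncol(p$mat))), con)
    apply(p$mat, 2, function(col) {
      writeLines(paste(sprintf("%.6f", col), collapse = "  "), con)
    })
  }
  invisible(path)
}

# Integer-scaled log-odds score matrix. A small pseudocount (a fraction of
# the background) keeps zero probabilities finite; scores are log2(p/bkg)
# scaled by `precision` and rounded, so the DP null distribution below is
# exact for the scores actually used in scanning.
pwm_int_scores <- function(p, precision = 100, pseudocount = 0.01) {
  pr <- (p$mat + pseudocount * p$bkg) / (1 + pseudocount)
  sc <- log2(pr / p$bkg)
  round(sc * precision)
}

#' Exact null distribution of PWM window scores
#'
#' Dynamic programming over motif positions under an independent-background
#' null: the distribution of the integer-scaled window score is built by
#' convolving, position by position, the four base scores weighted by the
#' background composition. Used to convert window scores into match
#' p-values `P(S >= s)`.
#'
#' @param p a `pwm`.
#' @param precision integer score scaling (default 100).
#' @return list with `score` (sorted integer scores), `prob`, and
#'   `p_value` (upper tail, inclusive).
#' @export
pwm_score_distribution <- function(p, precision = 100) {
  sc <- pwm_int_scores(p, precision)
  width <- sum(apply(sc, 2, max)) - sum(apply(sc, 2, min)) + 1L
  pmf <- numeric(width)
  shift0 <- -min(sc[, 1L])
  for (b in 1:4) {
    i <- sc[b, 1L] + shift0 + 1L
    pmf[i] <- pmf[i] + p$bkg[b]
  }
  lo <- min(sc[, 1L])
  for (j in seq_len(ncol(sc))[-1L]) {
    new <- numeric(width)
    idx <- which(pmf > 0)
    mj <- min(sc[, j])
    for (b in 1:4) {
      at <- idx + sc[b, j] - mj
      new[at] <- new[at] + pmf[idx] * p$bkg[b]
    }
    pmf <- new
    lo <- lo + mj
  }
  nz <- which(pmf > 0)
  score <- nz - 1L + lo
  prob <- pmf[nz]
  pv <- rev(cumsum(rev(prob)))
  list(score = score, prob = prob, p_value = pv)
}

# map a DNA string to integer codes A=1 C=2 G=3 T=4, N (and anything
# else) = 5
seq_to_int <- function(s) {
  v <- utf8ToInt(toupper(chartr("U", "T", s)))
  code <- rep(5L, 128L)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[v]
}

# integer window scores of one motif over one integer-coded sequence;
# N scores 0 (background) at any position
score_windows <- function(si, sc_int) {
  L <- ncol(sc_int); n <- length(si)
  if (n < L) return(integer(0))
  nw <- n - L + 1L
  tot <- integer(nw)
  scN <- rbind(sc_int, 0L)                    # 5th row: N contributes 0
  for (j in seq_len(L)) {
    tot <- tot + scN[si[j:(j + nw - 1L)], j]
  }
  tot
}

#' Scan sequences for PWM matches
#'
#' Slides each motif over each region sequence, scores windows by
#' background-normalised log-odds, converts scores into match p-values from
#' the exact null distribution ([pwm_score_distribution()]), and reports
#' windows with `p < p_cutoff` (strict, as in FIMO-style scanning). RNA
#' motifs are matched on the given (transcript-sense) strand only; `N`
#' bases contribute zero log-odds. Sequences shorter than the motif yield
#' no hits.
#'
#' @param regions `data.frame` with columns `event_id`, `region`, `seq`
#'   (see [extract_event_regions()]).
#' @param pwms list of `pwm` objects.
#' @param p_cutoff match p-value cutoff, default 0.001.
#' @param precision integer score scaling for the null DP.
#' @return `data.frame` of hits: `motif_id`, `event_id`, `region`, `offset`
#'   (1-based start within the region), `score` (log2 odds) and `p_value`.
#' @export
scan_motifs <- function(regions, pwms, p_cutoff = 0.001, precision = 100) {
  stopifnot(all(c("event_id", "region", "seq") %in% names(regions)),
            p_cutoff > 0, p_cutoff < 1)
  if (nrow(regions) == 0L || length(pwms) == 0L) {
    return(data.frame(motif_id = character(), event_id = character(),
                      region = character(), offset = integer(),
                      score = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  # concatenate all region sequences, separated by runs of N (which score
  # zero), and scan each motif in one vectorised pass; windows crossing a
  # region boundary are masked out
  seq_int <- lapply(regions$seq, seq_to_int)
  lens <- lengths(seq_int)
  gap <- max(vapply(pwms, function(p) ncol(p$mat), integer(1)))
  big <- integer(sum(lens) + gap * length(lens))
  starts <- integer(length(lens))
  pos <- 1L
  for (i in seq_along(seq_int)) {
    starts[i] <- pos
    if (lens[i] > 0) {
      big[pos:(pos + lens[i] - 1L)] <- seq_int[[i]]
    }
    big[(pos + lens[i]):(pos + lens[i] + gap - 1L)] <- 5L
    pos <- pos + lens[i] + gap
  }

  hits <- vector("list", length(pwms))
  for (k in seq_along(pwms)) {
    p <- pwms[[k]]
    sc <- pwm_int_scores(p, precision)
    L <- ncol(sc)
    null <- pwm_score_distribution(p, precision)
    ok <- null$p_value < p_cutoff
    if (!any(ok)) next
    thr <- min(null$score[ok])
    w <- score_windows(big, sc)
    valid <- logical(length(w))
    has_room <- lens >= L
    for (i in which(has_room)) {
      valid[starts[i]:(starts[i] + lens[i] - L)] <- TRUE
    }
    sel <- which(valid & w >= thr)
    if (length(sel)) {
      ridx <- findInterval(sel, starts)
      pv <- null$p_value[findInterval(w[sel], null$score)]
      hits[[k]] <- data.frame(
        motif_id = p$id, event_id = regions$event_id[ridx],
        region = regions$region[ridx],
        offset = sel - starts[ridx] + 1L,
        score = w[sel] / precision, p_value = pv,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(motif_id = character(), event_id = character(),
                      region = character(), offset = integer(),
                      score = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
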