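#' @include AllClasses.R
NULL

# character matrix of an alignment with non-ACGT coded NA (gaps/ambiguities
# are excluded from all site-wise computations: pairwise deletion)
alnMatrix <- function(aln) {
  m <- toupper(as.matrix(aln@seqs))
  m[!m %in% c("A", "C", "G", "T")] <- NA_character_
  m
}

subsetStratum <- function(aln, stratum) {
  if (is.null(stratum) || identical(stratum, "all")) return(seq_along(aln@deme))
  which(aln@deme %in% stratum)
}

#' Sequence diversity statistics for one locus
#'
#' Number of segregating sites S, haplotype count h, haplotype diversity
#' Hd = n/(n-1) (1 - sum p_k^2), and nucleotide diversity pi (mean pairwise
#' p-distance, pairwise deletion of gap/ambiguous sites).
#'
#' @param aln a \code{\linkS4class{HaplotypeAlignment}}.
#' @param stratum \code{NULL} or \code{"all"} for every haplotype, or a
#'   character vector of deme labels to restrict to.
#' @return named list with n, S, h, Hd, pi. Strata with fewer than two
#'   haplotypes give an error (undefined, never silently zero).
#' @examples
#' \dontrun{seqDiversity(aln, stratum = "EbuW")}
#' @export
seqDiversity <- function(aln, stratum = NULL) {
  idx <- subsetStratum(aln, stratum)
  abort_if(length(idx) < 2, "stratum must contain at least 2 haplotypes")
  m <- alnMatrix(aln)[idx, , drop = FALSE]
  n <- nrow(m)
  nAll <- apply(m, 2, function(col) length(unique(col[!is.na(col)])))
  S <- sum(nAll >= 2)
  # haplotypes: distinct sequences over scored sites
  key <- apply(m, 1, function(r) paste(ifelse(is.na(r), "N", r), collapse = ""))
  h <- length(unique(key))
  p <- table(key) / n
  Hd <- n / (n - 1) * (1 - sum(p^2))
  D <- seqDiffPairs(m)
  pi <- mean(D$dist / pmax(D$valid, 1))
  list(n = n, S = S, h = h, Hd = Hd, pi = pi)
}

# all pairwise difference counts + valid (co-scored) site counts
seqDiffPairs <- function(m) {
  n <- nrow(m)
  num <- matrix(0, n, n); val <- matrix(0L, n, n)
  obs <- !is.na(m)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- obs[i, ] & obs[j, ]
    d <- sum(m[i, ok] != m[j, ok])
    num[i, j] <- num[j, i] <- d
    val[i, j] <- val[j, i] <- sum(ok)
  }
  ut <- upper.tri(num)
  list(dist = num[ut], valid = val[ut], num = num, valid2 = val)
}

#' Pairwise sequence distance matrix
#'
#' Uncorrected distances between haplotypes with pairwise deletion of
#' gap/ambiguous sites.
#'
#' @param aln a \code{HaplotypeAlignment}.
#' @param scale \code{"persite"} for p-distances, \code{"count"} for
#'   difference counts rescaled to the full locus length
#'   (\code{diff * L / validSites}).
#' @return symmetric numeric matrix with haplotype labels as dimnames.
#' @export
seqDistMatrix <- function(aln, scale = c("persite", "count")) {
  scale <- match.arg(scale)
  m <- alnMatrix(aln)
  L <- ncol(m)
  dp <- seqDiffPairs(m)
  D <- dp$num / pmax(dp$valid2, 1)
  if (scale == "count") D <- D * L
  diag(D) <- 0
  dimnames(D) <- list(haplotypeLabels(aln), haplotypeLabels(aln))
  D
}

#' Tajima's D
#'
#' The classic neutrality statistic contrasting mean pairwise diversity with
#' Watterson's segregating-sites estimator:
#' \deqn{D = (\pi_T - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}}
#' with the canonical constants a1, a2, b1, b2, c1, c2, e1, e2 for sample
#' size n. \eqn{\pi_T} is the mean number of pairwise differences.
#'
#' @inheritParams seqDiversity
#' @return the D statistic (scalar); \code{NA} with attribute
#'   \code{"reason"} when S = 0 (undefined); error when n < 4.
#' @export
tajimasD <- function(aln, stratum = NULL) {
  idx <- subsetStratum(aln, stratum)
  n <- length(idx)
  abort_if(n < 4, "Tajima's D requires at least 4 sequences")
  m <- alnMatrix(aln)[idx, , drop = FALSE]
  nAll <- apply(m, 2, function(col) length(unique(col[!is.na(col)])))
  S <- sum(nAll >= 2)
  if (S == 0) return(structure(NA_real_, reason = "no segregating sites"))
  dp <- seqDiffPairs(m)
  piT <- mean(dp$dist)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piT - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Multilocus diversity table
#'
#' Per-stratum sequence statistics aggregated across loci: S and h are
#' summed over loci; Hd and pi are per-locus values averaged unweighted
#' (dnasp-like convention). With \code{concat = TRUE} the loci are
#' concatenated per haplotype label and a single set of statistics computed
#' on the concatenation instead.
#'
#' @param alignments list of \code{HaplotypeAlignment} (same individuals).
#' @param by group haplotypes by their deme label (default) or supply a
#'   named character vector mapping deme -> higher-level unit.
#' @param concat logical, concatenate loci instead of averaging.
#' @return data.frame with one row per stratum: n, S, h, Hd, pi.
#' @export
seqDiversityTable <- function(alignments, by = NULL, concat = FALSE) {
  abort_if(!length(alignments), "no alignments given")
  unitOf <- function(aln) {
    if (is.null(by)) aln@deme else unname(by[aln@deme])
  }
  units <- sort(unique(unlist(lapply(alignments, unitOf))))
  if (concat) {
    rows <- lapply(units, function(u) {
      parts <- lapply(alignments, function(a) {
        idx <- which(unitOf(a) == u)
        stats::setNames(as.character(a@seqs[idx]), haplotypeLabels(a)[idx])
      })
      labs <- Reduce(intersect, lapply(parts, names))
      seqs <- vapply(labs, function(l)
        paste(vapply(parts, function(p) p[[l]], ""), collapse = ""), "")
      aln <- new("HaplotypeAlignment", locusId = "concat",
                 seqs = Biostrings::DNAStringSet(unname(seqs)),
                 individual = labs, copy = rep(1L, length(labs)),
                 deme = rep(u, length(labs)))
      st <- seqDiversity(aln)
      data.frame(stratum = u, n = st$n, S = st$S, h = st$h, Hd = st$Hd,
                 pi = st$pi)
    })
    return(do.call(rbind, rows))
  }
  rows <- lapply(units, function(u) {
    per <- lapply(alignments, function(a) {
      idx <- which(unitOf(a) == u)
      if (length(idx) < 2) return(NULL)
      seqDiversity(new("HaplotypeAlignment", locusId = a@locusId,
                       seqs = a@seqs[idx], individual = a@individual[idx],
                       copy = a@copy[idx], deme = a@deme[idx]))
    })
    per <- per[!vapply(per, is.null, TRUE)]
    abort_if(!length(per), paste0("stratum '", u, "' has <2 haplotypes at every locus"))
    data.frame(stratum = u,
               n = max(vapply(per, function(x) x$n, 0)),
               S = sum(vapply(per, function(x) x$S, 0)),
               h = sum(vapply(per, function(x) x$h, 0)),
               Hd = mean(vapply(per, function(x) x$Hd, 0)),
               pi = mean(vapply(per, function(x) x$pi, 0)))
  })
  do.call(rbind, rows)
}
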