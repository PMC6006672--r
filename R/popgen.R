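# Within-family polymorphism statistics: Tajima's D with the TE copy number
# as the sample size, an ms-style neutral coalescent null for its
# significance, polymorphism shared between species, and copy-number
# variability across species.

# Tajima (1989) normalizing constants for sample size n.
.tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, e1 = e1, e2 = e2)
}

.tajima_d_from_counts <- function(n, S, pi) {
  k <- .tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (S == 0 || denom == 0) return(NA_real_)
  (pi - S / k$a1) / denom
}

#' Tajima's D and polymorphism summary of aligned TE copies
#'
#' Computes the number of segregating sites S, the mean number of pairwise
#' differences pi, Watterson's estimator S/a1 and Tajima's D over an
#' alignment of TE copies from one species, with the copy number as the
#' sample size. Sites containing a gap or N in any copy are excluded
#' listwise. D is undefined (NA) when S = 0, when n < 4, or when the
#' variance term vanishes.
#'
#' @param copies character vector of equal-length aligned copy sequences, or
#'   a character matrix (rows = copies)
#' @return list of class \code{"polymorphism_summary"}: \code{n}, \code{S},
#'   \code{pi}, \code{theta_w}, \code{tajima_d}, \code{sites_used}
#' @export
tajimas_d <- function(copies) {
  m <- .as_copy_matrix(copies)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 copies")
  bases <- c("A", "C", "G", "T")
  usable <- apply(m, 2, function(col) all(col %in% bases))
  m <- m[, usable, drop = FALSE]
  S <- 0L
  pi <- 0
  if (ncol(m) > 0) {
    npairs <- n * (n - 1) / 2
    for (j in seq_len(ncol(m))) {
      counts <- tabulate(match(m[, j], bases), 4L)
      if (sum(counts > 0) > 1L) {
        S <- S + 1L
        same <- sum(counts * (counts - 1) / 2)
        pi <- pi + (npairs - same) / npairs
      }
    }
  }
  a1 <- sum(1 / seq_len(n - 1))
  d <- if (n >= 4) .tajima_d_from_counts(n, S, pi) else NA_real_
  structure(list(n = n, S = S, pi = pi, theta_w = S / a1,
                 tajima_d = d, sites_used = ncol(m)),
            class = "polymorphism_summary")
}

#' @export
print.polymorphism_summary <- function(x, ...) {
  cat(sprintf("n = %d copies, %d sites: S = %d, pi = %.3f, thetaW = %.3f, D = %s\n",
              x$n, x$sites_used, x$S, x$pi, x$theta_w,
              if (is.na(x$tajima_d)) "undefined" else sprintf("%.3f", x$tajima_d)))
  invisible(x)
}

#' Neutral coalescent null distribution of Tajima's D
#'
#' Hudson-style neutral coalescent under the infinite-sites model: for each
#' replicate a Kingman genealogy of n lineages is drawn, S ~ Poisson(theta/2
#' x total branch length) mutations are placed proportionally to branch
#' length, and pi is accumulated from the derived-allele counts
#' (a mutation carried by k copies contributes k(n-k)/C(n,2)). Replicates
#' with S = 0 are recorded as undefined and excluded from quantiles, with a
#' logged count.
#'
#' @param n sample size (copy number), >= 4
#' @param theta scaled mutation rate for the whole sequence
#' @param n_reps number of replicates
#' @param seed integer seed
#' @return list of class \code{"null_distribution"}: \code{d} (replicate D
#'   values, NA where S = 0), \code{s} (replicate segregating sites),
#'   \code{n}, \code{theta}, \code{n_reps}, \code{n_undefined}
#' @export
coalescent_null <- function(n, theta, n_reps = 1000L, seed = NULL) {
  if (n < 4) stop("n must be >= 4 for Tajima's D")
  if (theta <= 0) stop("theta must be > 0")
  if (!is.null(seed)) set.seed(seed)
  npairs <- n * (n - 1) / 2
  d <- numeric(n_reps)
  s <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    gen <- .coalescent_segments(n)
    S <- stats::rpois(1, theta / 2 * sum(gen$dur))
    s[r] <- S
    if (S == 0) { d[r] <- NA_real_; next }
    seg <- sample.int(length(gen$dur), S, replace = TRUE, prob = gen$dur)
    k <- gen$size[seg]
    pi <- sum(k * (n - k)) / npairs
    d[r] <- .tajima_d_from_counts(n, S, pi)
  }
  structure(list(d = d, s = s, n = n, theta = theta, n_reps = n_reps,
                 n_undefined = sum(is.na(d))),
            class = "null_distribution")
}

#' One-sided (lower-tail) empirical p-value for Tajima's D
#'
#' p = (1 + number of null replicates <= observed) / (1 + defined
#' replicates): the probability, under neutrality, of a D as low as or lower
#' than observed, with the add-one correction so p is never exactly zero.
#'
#' @param observed observed Tajima's D
#' @param null a \code{\link{coalescent_null}} result (or numeric vector of
#'   null D replicates)
#' @param min_defined minimum number of defined replicates required
#' @return the one-sided p-value
#' @export
tajima_p <- function(observed, null, min_defined = 100L) {
  reps <- if (inherits(null, "null_distribution")) null$d else null
  reps <- reps[!is.na(reps)]
  if (length(reps) < min_defined)
    stop("only ", length(reps), " defined null replicates (need >= ",
         min_defined, ")")
  (1 + sum(reps <= observed)) / (1 + length(reps))
}

.polymorphic_sites <- function(m) {
  bases <- c("A", "C", "G", "T")
  res <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    al <- unique(col[col %in% bases])
    if (length(al) > 1L) al else NULL
  })
  names(res) <- seq_len(ncol(m))
  res[!vapply(res, is.null, logical(1))]
}

#' Polymorphism shared between two species' copies of one family
#'
#' Both alignments must be on the same family coordinate frame (equal column
#' count). A site is shared when it is polymorphic in both species and the
#' two species' segregating allele sets overlap in at least two alleles; the
#' denominator is the union of sites polymorphic in either species (the
#' \code{"sum"} convention counts each species' polymorphic sites
#' separately).
#'
#' @param copies_a,copies_b aligned copy sets of the two species
#' @param denominator \code{"union"} (default) or \code{"sum"}
#' @return list of class \code{"shared_polymorphism"}: \code{shared_sites},
#'   \code{union_sites}, \code{proportion} (NA with \code{reason} when no
#'   polymorphism exists in either species)
#' @export
shared_polymorphism <- function(copies_a, copies_b,
                                denominator = c("union", "sum")) {
  denominator <- match.arg(denominator)
  ma <- .as_copy_matrix(copies_a)
  mb <- .as_copy_matrix(copies_b)
  if (ncol(ma) != ncol(mb))
    stop("alignments are on different coordinate frames (",
         ncol(ma), " vs ", ncol(mb), " columns)")
  pa <- .polymorphic_sites(ma)
  pb <- .polymorphic_sites(mb)
  both <- intersect(names(pa), names(pb))
  shared <- sum(vapply(both, function(j)
    length(intersect(pa[[j]], pb[[j]])) >= 2L, logical(1)))
  denom <- if (denominator == "union")
    length(union(names(pa), names(pb))) else length(pa) + length(pb)
  out <- list(shared_sites = as.integer(shared),
              union_sites = as.integer(denom),
              proportion = if (denom > 0) shared / denom else NA_real_,
              reason = if (denom > 0) NA_character_
                       else "no polymorphism in either species")
  class(out) <- "shared_polymorphism"
  out
}

#' Coefficient of variation of per-species copy numbers
#'
#' @param values copy numbers across species (>= 2 values, positive mean)
#' @return sample standard deviation / mean
#' @export
copy_number_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 copy-number values")
  m <- mean(values)
  if (m <= 0) stop("mean copy number must be > 0")
  stats::sd(values) / m
}

#' Spearman rank correlation
#'
#' Wrapper around \code{stats::cor.test(method = "spearman")} returning rho
#' and its p-value; rho is NA for constant input.
#'
#' @param x,y paired numeric vectors of length >= 4
#' @return list with \code{rho} and \code{p}
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 4L) stop("need at least 4 pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
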