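# Horizontal-transfer classification: a TE family's synonymous divergence
# between two species is compared against the distribution of synonymous
# divergence of the species pair's nuclear genes. Because dS is approximately
# neutral it is comparable between TEs and genes; a TE transmitted vertically
# since the species split should match the genic distribution, whereas a
# recently transferred TE sits far below it.

#' Empirical quantile (type-7 linear interpolation)
#'
#' @param values numeric vector (non-empty, NAs dropped)
#' @param q probability in [0, 1]
#' @return the quantile value
#' @export
empirical_quantile <- function(values, q) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty vector")
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  unname(stats::quantile(values, probs = q, type = 7))
}

#' Genic dS distribution for one species pair
#'
#' Holds the per-gene synonymous divergences and the two quantiles the
#' classifier uses (2.5% and 50% by default). Saturated/undefined values
#' (NA) are dropped with a recorded count.
#'
#' @param ds_values per-gene dS for the pair
#' @param species_pair optional label, e.g. \code{"pse-per"}
#' @param q_strong,q_median classifier quantile probabilities
#' @return list of class \code{"genic_ds"} with \code{ds_values},
#'   \code{q_lower}, \code{q_median}, \code{n_dropped}
#' @export
genic_ds_distribution <- function(ds_values, species_pair = NA_character_,
                                  q_strong = 0.025, q_median = 0.5) {
  n_dropped <- sum(is.na(ds_values))
  ds <- ds_values[!is.na(ds_values)]
  if (length(ds) == 0L) stop("no defined genic dS values")
  if (any(ds < 0)) stop("negative dS values in genic set")
  if (length(ds) < 40L)
    warning("only ", length(ds), " genic dS values; the ", q_strong * 100,
            "% quantile is unstable below 40")
  structure(list(species_pair = species_pair, ds_values = ds,
                 q_lower = empirical_quantile(ds, q_strong),
                 q_median = empirical_quantile(ds, q_median),
                 n_dropped = n_dropped),
            class = "genic_ds")
}

#' Classify TE families against the genic dS quantiles
#'
#' A family shows \emph{strong} evidence of horizontal exchange when its dS is
#' strictly below the genic 2.5% quantile, has \emph{potentially} transferred
#' when its dS lies between the 2.5% and 50% quantiles (both ends inclusive),
#' and shows \emph{no} evidence when above the median. Undefined (saturated)
#' TE dS gives category \code{"undefined"}. Boundary ties resolve toward the
#' weaker category.
#'
#' @param te_ds numeric vector of TE dS values (NA = undefined)
#' @param genic a \code{\link{genic_ds_distribution}} (or numeric vector of
#'   genic dS, converted with defaults)
#' @return factor with levels \code{strong}, \code{potential}, \code{none},
#'   \code{undefined}, one per element of \code{te_ds}
#' @export
classify_htt <- function(te_ds, genic) {
  if (!inherits(genic, "genic_ds")) genic <- genic_ds_distribution(genic)
  out <- ifelse(is.na(te_ds), "undefined",
         ifelse(te_ds < genic$q_lower, "strong",
         ifelse(te_ds <= genic$q_median, "potential", "none")))
  factor(out, levels = c("strong", "potential", "none", "undefined"))
}

#' ENC-conditioned confirmation of a putative transfer
#'
#' Selection on codon usage depresses apparent dS, so low TE dS alone can be
#' a false signal. The confirmation rule conditions on the effective number
#' of codons: the TE is confirmed when its dS lies more than \code{k}
#' standard deviations below the mean genic dS of genes with similar ENC
#' (those within a sliding window of \code{window_width} ENC units centred on
#' the TE's Nc).
#'
#' @param te_ds,te_nc the TE's dS and effective number of codons
#' @param genic_ds,genic_nc paired vectors for the genic set
#' @param window_width width of the ENC window (units of Nc)
#' @param k standard-deviation multiplier
#' @param min_window minimum genic points required in the window
#' @return list with \code{confirmed} (TRUE/FALSE/NA), \code{flag}
#'   (\code{"ok"}, \code{"insufficient window"} or \code{"no ENC"}),
#'   \code{window_n}, \code{window_mean}, \code{window_sd}
#' @export
enc_conditioned_test <- function(te_ds, te_nc, genic_ds, genic_nc,
                                 window_width = 5, k = 2, min_window = 5L) {
  if (length(genic_ds) != length(genic_nc))
    stop("genic_ds and genic_nc must be paired")
  if (is.na(te_nc))
    return(list(confirmed = NA, flag = "no ENC", window_n = 0L,
                window_mean = NA_real_, window_sd = NA_real_))
  keep <- !is.na(genic_ds) & !is.na(genic_nc) &
    abs(genic_nc - te_nc) <= window_width / 2
  w <- genic_ds[keep]
  if (length(w) < min_window)
    return(list(confirmed = NA, flag = "insufficient window",
                window_n = length(w), window_mean = NA_real_,
                window_sd = NA_real_))
  m <- mean(w); s <- stats::sd(w)
  list(confirmed = !is.na(te_ds) && te_ds < m - k * s, flag = "ok",
       window_n = length(w), window_mean = m, window_sd = s)
}

#' Neighbor-joining tree from a pairwise distance matrix
#'
#' Thin wrapper around \code{ape::nj} with validation and with negative
#' branch lengths clamped to zero, used to build per-family trees from
#' pairwise dS matrices.
#'
#' @param d symmetric numeric matrix with zero diagonal and species labels
#'   as dimnames, or a \code{dist}
#' @return unrooted \code{phylo}
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("negative distances")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Robinson-Foulds discordance between a family tree and the species tree
#'
#' @param family_tree,species_tree \code{phylo} objects over the same tips
#' @return list with \code{rf} (the unrooted RF distance) and
#'   \code{discordant} (\code{rf > 0})
#' @export
rf_discordance <- function(family_tree, species_tree) {
  a <- sort(family_tree$tip.label); b <- sort(species_tree$tip.label)
  if (!identical(a, b)) {
    only_a <- setdiff(a, b); only_b <- setdiff(b, a)
    stop("tip sets differ: family-only {", paste(only_a, collapse = ","),
         "}, species-only {", paste(only_b, collapse = ","), "}")
  }
  rf <- phangorn::RF.dist(ape::unroot(family_tree), ape::unroot(species_tree))
  list(rf = as.integer(rf), discordant = rf > 0)
}

#' Build an HTT call table for families across species pairs
#'
#' Convenience constructor producing one row per family x pair with the
#' quantile category and optional confirmation/discordance flags.
#'
#' @param family_id,species_pair,te_ds parallel vectors
#' @param category factor from \code{\link{classify_htt}}
#' @param enc_confirmed,discordant optional logical vectors (NA when not
#'   assessed)
#' @return data.frame of class \code{c("htt_calls", "data.frame")}
#' @export
htt_calls <- function(family_id, species_pair, te_ds, category,
                      enc_confirmed = NA, discordant = NA) {
  n <- length(family_id)
  if (length(enc_confirmed) == 1L) enc_confirmed <- rep(enc_confirmed, n)
  if (length(discordant) == 1L) discordant <- rep(discordant, n)
  out <- data.frame(family_id = family_id, species_pair = species_pair,
                    te_ds = te_ds, category = category,
                    enc_confirmed = enc_confirmed, discordant = discordant,
                    stringsAsFactors = FALSE)
  class(out) <- c("htt_calls", "data.frame")
  out
}

#' Summarize transfer calls per species pair and per family
#'
#' @param calls an \code{\link{htt_calls}} table
#' @return list with \code{per_pair} (counts of each category by pair),
#'   \code{strong_all_pairs} (families strong in every pair they appear in,
#'   requiring at least one pair), and \code{none_all_pairs}
#' @export
summarize_transfers <- function(calls) {
  if (nrow(calls) == 0L)
    return(list(per_pair = data.frame(species_pair = character(0),
                                      strong = integer(0),
                                      potential = integer(0),
                                      none = integer(0),
                                      undefined = integer(0)),
                strong_all_pairs = character(0),
                none_all_pairs = character(0)))
  tab <- table(calls$species_pair, factor(calls$category,
               levels = c("strong", "potential", "none", "undefined")))
  per_pair <- data.frame(species_pair = rownames(tab),
                         strong = as.integer(tab[, "strong"]),
                         potential = as.integer(tab[, "potential"]),
                         none = as.integer(tab[, "none"]),
                         undefined = as.integer(tab[, "undefined"]),
                         stringsAsFactors = FALSE, row.names = NULL)
  all_in <- function(cat) {
    by_fam <- split(as.character(calls$category), calls$family_id)
    names(by_fam)[vapply(by_fam, function(x) length(x) > 0 && all(x == cat),
                         logical(1))]
  }
  list(per_pair = per_pair,
       strong_all_pairs = all_in("strong"),
       none_all_pairs = all_in("none"))
}
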