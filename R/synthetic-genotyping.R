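#' Generate a synthetic genotyping run
#'
#' Emulates a diverse-panel KASP genotyping experiment: samples drawn from
#' `k` planted subpopulations with group-specific target-allele frequencies,
#' per-marker outcome classes (a fraction of markers fails in every sample,
#' a small fraction is shaky with elevated per-call failure, a small
#' fraction is monomorphic), call-level failure codes split among `?`,
#' `Bad` and `Uncallable`, and optional design lines whose calls are the
#' design-time predictions perturbed at per-line discordance rates (one
#' strongly drifted line emulating a seed-lot divergence).
#'
#' Defaults mirror the study conditions of the validation run this package
#' models: 178 samples, 4 subpopulations, ~16% of markers failing in all
#' samples, validation at a call rate above 90%.
#'
#' @param markers Character vector of marker ids.
#' @param seed Integer seed.
#' @param n_samples Number of diversity-panel samples (default 178).
#' @param k Number of subpopulations (default 4).
#' @param group_props Group mixing proportions (sums to 1).
#' @param all_fail_rate Fraction of markers failing in every sample
#'   (default 0.159).
#' @param shaky_rate Fraction of markers with elevated, variable per-call
#'   failure (default 0.005).
#' @param mono_rate Fraction of markers monomorphic in the panel
#'   (default 0.003).
#' @param call_fail_rate Baseline per-call failure probability
#'   (default 0.02).
#' @param beta_shape Shape of the Beta distribution for group allele
#'   frequencies; small values give strong divergence (default 0.2).
#' @param design_predicted Optional tibble `sample`, `marker`, `predicted`
#'   (values `reference`/`target`/`het`/`unknown`) for design lines to add.
#' @param discord_rates Optional named per-line discordance rates for the
#'   design lines; default: one drifted line at 0.535, one at 0.26, the
#'   rest drawn from U(0.02, 0.12).
#' @return List: `gm` (long genotype tibble), `truth` (list with `groups`
#'   named group labels, `marker_category` tibble, `cells` tibble with the
#'   true genotype and failure flag per cell, `discord_rates`).
#' @export
sim_genotyping <- function(markers, seed = 1, n_samples = 178, k = 4,
                           group_props = c(0.55, 0.2, 0.15, 0.1),
                           all_fail_rate = 0.159, shaky_rate = 0.005,
                           mono_rate = 0.003, call_fail_rate = 0.02,
                           beta_shape = 0.2, design_predicted = NULL,
                           discord_rates = NULL) {
  set.seed(seed)
  stopifnot(length(group_props) == k, abs(sum(group_props) - 1) < 1e-8)
  M <- length(markers)
  samples <- sprintf("S%03d", seq_len(n_samples))
  groups <- sample(seq_len(k), n_samples, replace = TRUE, prob = group_props)
  names(groups) <- samples

  cat_draw <- stats::runif(M)
  category <- ifelse(cat_draw < all_fail_rate, "all_fail",
              ifelse(cat_draw < all_fail_rate + shaky_rate, "shaky",
              ifelse(cat_draw < all_fail_rate + shaky_rate + mono_rate,
                     "monomorphic", "normal")))
  # group-specific target-allele frequencies
  p <- matrix(stats::rbeta(k * M, beta_shape, beta_shape), nrow = k)
  p[, category == "monomorphic"] <- 0
  shaky_fail <- stats::runif(M, 0.05, 0.60)

  grid <- tidyr::crossing(sample = samples, marker = markers)
  gidx <- groups[grid$sample]
  midx <- match(grid$marker, markers)
  pcell <- p[cbind(gidx, midx)]
  dosage <- stats::rbinom(nrow(grid), 2, pcell)
  true_call <- c("ref_hom", "het", "alt_hom")[dosage + 1]

  fail_p <- ifelse(category[midx] == "all_fail", 1,
            ifelse(category[midx] == "shaky", shaky_fail[midx],
                   call_fail_rate))
  failed <- stats::runif(nrow(grid)) < fail_p
  fcode <- sample(c("?", "Bad", "Uncallable"), nrow(grid), replace = TRUE,
                  prob = c(0.90, 0.06, 0.04))
  call <- ifelse(failed, fcode, true_call)
  gm <- tibble::tibble(sample = grid$sample, marker = grid$marker,
                       call = call)
  cells <- tibble::tibble(sample = grid$sample, marker = grid$marker,
                          true_call = true_call, failed = failed)

  truth <- list(groups = groups,
                marker_category = tibble::tibble(marker = markers,
                                                 category = category),
                cells = cells, discord_rates = NULL)

  if (!is.null(design_predicted)) {
    lines <- sort(unique(design_predicted$sample))
    if (is.null(discord_rates)) {
      n_l <- length(lines)
      base <- stats::runif(max(0, n_l - 2), 0.02, 0.12)
      discord_rates <- stats::setNames(
        c(base, 0.26, 0.535)[seq_len(n_l)], lines)
    }
    dp <- design_predicted[design_predicted$marker %in% markers, , drop = FALSE]
    exp_call <- dplyr::recode(dp$predicted, reference = "ref_hom",
                              target = "alt_hom", het = "het",
                              .default = NA_character_)
    # discord: replace by a different successful code; lines whose design-time
    # state is unresolvable ("unknown") still yield an ordinary call
    flip <- stats::runif(nrow(dp)) < discord_rates[dp$sample]
    alt_code <- vapply(exp_call, function(e) {
      sample(setdiff(c("ref_hom", "alt_hom", "het"), e), 1)
    }, character(1))
    callL <- ifelse(is.na(exp_call),
                    sample(c("ref_hom", "alt_hom", "het"), nrow(dp),
                           replace = TRUE, prob = c(0.45, 0.45, 0.10)),
                    ifelse(flip, alt_code, exp_call))
    # the same per-marker failure model applies to design lines
    midx_l <- match(dp$marker, markers)
    fail_p_l <- ifelse(category[midx_l] == "all_fail", 1,
                ifelse(category[midx_l] == "shaky", shaky_fail[midx_l],
                       call_fail_rate))
    cfail <- stats::runif(nrow(dp)) < fail_p_l
    fcodeL <- sample(c("?", "Bad", "Uncallable"), nrow(dp), replace = TRUE,
                     prob = c(0.90, 0.06, 0.04))
    callL <- ifelse(cfail, fcodeL, callL)
    gm <- dplyr::bind_rows(gm, tibble::tibble(sample = dp$sample,
                                              marker = dp$marker,
                                              call = callL))
    truth$discord_rates <- discord_rates
  }
  list(gm = gm, truth = truth)
}
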