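#' Simulation configuration
#'
#' Parameters of the synthetic TMT experiment generator. Defaults emulate the
#' study design the pipeline targets: 4 wild-type vs 5 homozygous reporter
#' channels, several peptides per protein, a modest fraction of regulated
#' proteins with lognormal effect magnitudes, per-peptide ionization
#' efficiency, multiplicative lognormal measurement noise, a small fraction of
#' shared (two-owner) peptides and intensity-dependent missingness.
#'
#' @param n_proteins Number of proteins. Default 500.
#' @param peptides_per_protein Integer range `c(lo, hi)`; each protein draws
#'   its peptide count uniformly from it. Lower bound must be >= 1.
#'   Default `c(2, 8)`.
#' @param n_wt,n_hom Channels per group. Defaults 4 and 5.
#' @param frac_regulated Proportion of proteins with a true Hom/Wt ratio != 1.
#'   Default 0.2.
#' @param log2fc_magnitude `c(mean, sd)` of the (positive) log2 effect
#'   magnitude of regulated proteins; direction is split 50/50 up/down.
#'   Default `c(1, 0.3)`.
#' @param ionization_sd Lognormal sd (log scale) of per-peptide ionization
#'   efficiency. Default 1.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise. Default 0.1.
#' @param frac_shared_peptides Proportion of peptides assigned a second owner
#'   protein (and therefore excluded from rollup). Default 0.05.
#' @param missing_rate Overall proportion of intensity cells blanked;
#'   missingness is intensity-dependent (logistic in log intensity), so low
#'   intensities are blanked preferentially. Default 0.05.
#' @param seed Integer seed; all draws flow from one generator stream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 500L,
                       peptides_per_protein = c(2L, 8L),
                       n_wt = 4L, n_hom = 5L,
                       frac_regulated = 0.2,
                       log2fc_magnitude = c(1, 0.3),
                       ionization_sd = 1,
                       noise_cv = 0.1,
                       frac_shared_peptides = 0.05,
                       missing_rate = 0.05,
                       seed = 1L) {
  stopifnot(
    is_count(n_proteins), n_proteins >= 1,
    length(peptides_per_protein) == 2L,
    peptides_per_protein[1L] <= peptides_per_protein[2L],
    is_count(n_wt), n_wt >= 2, is_count(n_hom), n_hom >= 2,
    frac_regulated >= 0, frac_regulated <= 1,
    length(log2fc_magnitude) == 2L, log2fc_magnitude[2L] >= 0,
    ionization_sd >= 0, noise_cv >= 0,
    frac_shared_peptides >= 0, frac_shared_peptides <= 1,
    missing_rate >= 0, missing_rate < 1
  )
  if (peptides_per_protein[1L] < 1)
    stop("every protein needs at least 1 peptide", call. = FALSE)
  structure(list(
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    n_wt = as.integer(n_wt), n_hom = as.integer(n_hom),
    frac_regulated = frac_regulated,
    log2fc_magnitude = log2fc_magnitude,
    ionization_sd = ionization_sd, noise_cv = noise_cv,
    frac_shared_peptides = frac_shared_peptides,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a TMT peptide-intensity dataset with known ground truth
#'
#' Generates a peptide x sample reporter-intensity matrix under a
#' multiplicative model: the intensity of peptide j (owned by protein k) in
#' sample i is the protein's base abundance in sample i's group, times the
#' peptide's ionization efficiency, times lognormal noise. Base abundances are
#' drawn log-uniformly over three orders of magnitude; regulated proteins
#' multiply their Hom abundance by the drawn true ratio. A fraction of
#' peptides is shared between exactly two proteins (their signal is the sum of
#' both owners' contributions); a fraction of cells is blanked with
#' probability decreasing in log intensity, calibrated so the overall blanked
#' proportion matches `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{peptides}{a [peptide_matrix()] (groups `Wt`/`Hom`)}
#'     \item{map}{peptide-to-protein mapping data.frame (shared peptides on
#'       two rows)}
#'     \item{truth}{a data.frame with per-protein `protein_id`, `true_ratio`
#'       (Hom/Wt), `regulated` label (`Up`/`Down`/`NS`), plus attributes
#'       `shared_peptides` (character) and `config`}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 20, seed = 7))
#' sim$peptides
#' table(sim$truth$regulated)
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    np <- config$n_proteins
    protein_ids <- sprintf("PROT%04d", seq_len(np))
    n_samples <- config$n_wt + config$n_hom
    groups <- c(rep("Wt", config$n_wt), rep("Hom", config$n_hom))
    sample_ids <- c(sprintf("Wt%d", seq_len(config$n_wt)),
                    sprintf("Hom%d", seq_len(config$n_hom)))

    # protein-level truth: base abundance over 3 decades, planted ratios
    base <- 10 ^ runif(np, 4, 7)
    n_reg <- round(config$frac_regulated * np)
    reg_idx <- if (n_reg > 0) sample.int(np, n_reg) else integer()
    up <- rep(FALSE, np)
    if (n_reg > 0)                      # 50/50 split of directions
      up[reg_idx] <- sample(rep(c(TRUE, FALSE), length.out = n_reg))
    mag <- abs(rnorm(np, config$log2fc_magnitude[1L],
                     config$log2fc_magnitude[2L]))
    true_ratio <- rep(1, np)
    true_ratio[reg_idx] <- ifelse(up[reg_idx], 2 ^ mag[reg_idx],
                                  2 ^ -mag[reg_idx])
    regulated <- rep("NS", np)
    regulated[reg_idx] <- ifelse(up[reg_idx], "Up", "Down")

    # peptide layout
    n_pep <- sample(seq.int(config$peptides_per_protein[1L],
                            config$peptides_per_protein[2L]),
                    np, replace = TRUE)
    owner1 <- rep.int(seq_len(np), n_pep)
    total_pep <- length(owner1)
    peptide_ids <- sprintf("PEP%05d", seq_len(total_pep))
    n_shared <- round(config$frac_shared_peptides * total_pep)
    shared_idx <- if (n_shared > 0) sample.int(total_pep, n_shared) else integer()
    owner2 <- rep(NA_integer_, total_pep)
    if (n_shared > 0 && np >= 2) {
      # second owner differs from the first
      o2 <- vapply(owner1[shared_idx], function(o1)
        sample(seq_len(np)[-o1], 1L), 1L)
      owner2[shared_idx] <- o2
    }

    eff <- rlnorm(total_pep, 0, config$ionization_sd)
    sdlog <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0

    group_ratio <- rbind(Wt = rep(1, np), Hom = true_ratio)
    signal <- base[owner1] * eff            # per peptide, group-neutral part
    intens <- matrix(NA_real_, nrow = total_pep, ncol = n_samples,
                     dimnames = list(peptide_ids, sample_ids))
    for (i in seq_len(n_samples)) {
      g <- groups[i]
      x <- signal * group_ratio[g, owner1]
      sh <- which(!is.na(owner2))
      if (length(sh))
        x[sh] <- x[sh] + base[owner2[sh]] * eff[sh] * group_ratio[g, owner2[sh]]
      if (sdlog > 0)
        x <- x * rlnorm(total_pep, -sdlog^2 / 2, sdlog)
      intens[, i] <- x
    }

    # intensity-dependent missingness: logistic in -log10 intensity, offset
    # calibrated so the mean blanking probability equals missing_rate
    if (config$missing_rate > 0) {
      z <- -log10(intens)
      z <- (z - mean(z)) / max(sd(z), .Machine$double.eps)
      f <- function(a) mean(plogis(a + z)) - config$missing_rate
      a <- uniroot(f, c(-50, 50))$root
      blank <- matrix(runif(length(intens)) < plogis(a + z),
                      nrow = nrow(intens))
      intens[blank] <- NA_real_
    }

    map <- data.frame(
      peptide_id = c(peptide_ids, peptide_ids[shared_idx]),
      protein_id = c(protein_ids[owner1], protein_ids[owner2[shared_idx]]),
      stringsAsFactors = FALSE)
    map <- map[order(map$peptide_id, map$protein_id), ]
    rownames(map) <- NULL

    truth <- data.frame(protein_id = protein_ids, true_ratio = true_ratio,
                        regulated = regulated, stringsAsFactors = FALSE)
    attr(truth, "shared_peptides") <- peptide_ids[shared_idx]
    attr(truth, "config") <- config

    list(peptides = peptide_matrix(intens, groups), map = map, truth = truth)
  })
}

#' Simulate term annotations matched to a simulated ground truth
#'
#' Builds `n_terms` protein sets over the simulated proteome. When
#' `enrichment_bias > 1`, the first term is "planted": its members are sampled
#' with probability weight `enrichment_bias` for regulated proteins and 1
#' otherwise, so it should surface as the top enriched term downstream. All
#' other terms sample members uniformly.
#'
#' @param truth Ground-truth data.frame from [simulate_dataset()].
#' @param n_terms Number of terms to generate.
#' @param term_size Integer range `c(lo, hi)` of members per term.
#' @param enrichment_bias Odds multiplier (>= 1) favouring regulated proteins
#'   in the planted term. Default 1 (no planted signal).
#' @param category Category label for the generated terms. Default `"pathway"`.
#' @param seed Integer seed.
#' @return A list of terms in the [read_annotation_gmt()] shape; when a term
#'   is planted its `term_id` is also stored in the `planted` attribute.
#' @export
simulate_annotations <- function(truth, n_terms, term_size = c(10L, 40L),
                                 enrichment_bias = 1, category = "pathway",
                                 seed = 1L) {
  stopifnot(is_count(n_terms), length(term_size) == 2L,
            term_size[1L] <= term_size[2L], enrichment_bias >= 1)
  if (n_terms == 0L) return(list())
  np <- nrow(truth)
  if (term_size[2L] > np)
    stop("term_size exceeds the number of proteins", call. = FALSE)
  with_seed(seed, {
    terms <- vector("list", n_terms)
    w_reg <- ifelse(truth$regulated != "NS", enrichment_bias, 1)
    for (t in seq_len(n_terms)) {
      size <- sample(seq.int(term_size[1L], term_size[2L]), 1L)
      w <- if (t == 1L && enrichment_bias > 1) w_reg else rep(1, np)
      members <- truth$protein_id[sample.int(np, size, prob = w)]
      terms[[t]] <- list(term_id = sprintf("TERM%03d", t),
                         name = sprintf("simulated term %d", t),
                         category = category, members = members)
    }
    if (enrichment_bias > 1) attr(terms, "planted") <- terms[[1L]]$term_id
    terms
  })
}

#' Degrade one sample channel
#'
#' Replaces the named sample's intensities, for a given fraction of peptides,
#' with independent draws from that channel's own empirical intensity
#' distribution, destroying its correlation with the other replicates. Used
#' to create a planted non-reproducible channel for QC testing.
#'
#' @param x A [peptide_matrix()].
#' @param sample_id Name of the sample column to degrade.
#' @param decorrelation Proportion of that sample's peptides to re-draw,
#'   in \[0, 1\].
#' @param seed Integer seed.
#' @return The modified `peptide_matrix`.
#' @export
degrade_sample <- function(x, sample_id, decorrelation, seed = 1L) {
  stopifnot(inherits(x, "peptide_matrix"),
            decorrelation >= 0, decorrelation <= 1)
  if (!sample_id %in% colnames(x))
    stop("unknown sample: ", sample_id, call. = FALSE)
  if (decorrelation == 0) return(x)
  with_seed(seed, {
    col <- x[, sample_id]
    obs <- which(!is.na(col))
    n_redraw <- round(decorrelation * length(obs))
    if (n_redraw > 0) {
      idx <- sample(obs, n_redraw)
      x[idx, sample_id] <- sample(col[obs], n_redraw, replace = TRUE)
    }
    x
  })
}
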