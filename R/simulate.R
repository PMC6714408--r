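#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 357 rheumatoid-arthritis patients on a TNF-alpha blocker, a
#' low-frequency (5.6% carrier) intergenic deletion at 2q14.3 whose
#' carriers have strongly elevated odds of EULAR non-response (adjusted
#' odds ratio about 8.44), baseline DAS28 around 6.24 (SD 0.89), roughly
#' 9% non-responders, drug mix adalimumab/etanercept/golimumab/infliximab
#' of 16.8/72.8/5.3/5.0%, and a background of random CNVs with per-sample
#' boundary jitter.
#'
#' @param n_samples cohort size (>= 2).
#' @param causal_carrier_freq fraction of samples carrying at least one
#'   deleted allele at the causal locus, in (0, 1).
#' @param causal_region list with `chromosome`, `start`, `end` (bp).
#' @param effect_log_or log odds ratio of non-response per deletion
#'   carrier.
#' @param baseline_nr_prob non-response probability for a non-carrier with
#'   average covariates.
#' @param background_cnv_rate mean number of background CNVs per sample
#'   (Poisson).
#' @param boundary_jitter_sd SD (bp) of the rounded-Normal jitter applied
#'   to causal-call endpoints.
#' @param n_pcs number of genetic principal components generated.
#' @param seed integer seed; identical configs give identical output.
#' @param drug_props named proportions of the four TNF-alpha blockers.
#' @param moderate_frac fraction of responders labelled moderate (the rest
#'   good).
#' @param covariate_effects named list of log-odds effects placed on the
#'   covariates in the generative non-response model (`bmi` per kg/m2
#'   above 23.5, `sex`, `mtx`, `das28` per DAS28 unit above 6.24, `pc` per
#'   PC unit, `drug` per-category offsets).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 357,
                       causal_carrier_freq = 0.056,
                       causal_region = list(chromosome = "2",
                                            start = 129457798,
                                            end = 129461606),
                       effect_log_or = log(8.44),
                       baseline_nr_prob = 0.08,
                       background_cnv_rate = 2,
                       boundary_jitter_sd = 200,
                       n_pcs = 5,
                       seed = 1,
                       drug_props = c(adalimumab = 0.168, etanercept = 0.728,
                                      golimumab = 0.053, infliximab = 0.050),
                       moderate_frac = 208 / 325,
                       covariate_effects = list(
                         bmi = 0.02, sex = 0.15, mtx = -0.15, das28 = 0.15,
                         pc = 0.10,
                         drug = c(adalimumab = 0.10, etanercept = 0,
                                  golimumab = -0.10, infliximab = 0.10))) {
  if (n_samples < 2) stop("invalid n_samples: must be >= 2")
  if (causal_carrier_freq <= 0 || causal_carrier_freq >= 1)
    stop("invalid causal_carrier_freq: must be in (0, 1)")
  if (baseline_nr_prob <= 0 || baseline_nr_prob >= 1)
    stop("invalid baseline_nr_prob: must be in (0, 1)")
  if (boundary_jitter_sd < 0) stop("invalid boundary_jitter_sd: must be >= 0")
  if (background_cnv_rate < 0) stop("invalid background_cnv_rate: must be >= 0")
  if (n_pcs < 0) stop("invalid n_pcs: must be >= 0")
  if (any(drug_props < 0) || sum(drug_props) <= 0)
    stop("invalid drug_props: must be nonnegative with positive sum")
  drug_props <- drug_props / sum(drug_props)  # printed cohort %s sum to 99.9
  if (causal_region$start > causal_region$end)
    stop("invalid causal_region: start > end")
  structure(as.list(environment()), class = "sim_config")
}

#' Default scaled-down genome map for background CNV placement
#'
#' Twenty-two autosomes of 50 Mb each: large enough that random background
#' CNVs essentially never recur across samples, small enough to keep
#' simulations light.
#'
#' @return data.frame with `chromosome` and `length` (bp).
#' @export
default_genome_map <- function() {
  data.frame(chromosome = as.character(1:22), length = 5e7,
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort
#'
#' Draws, in order: true deletion genotypes at the causal locus under
#' Hardy-Weinberg (allele frequency `1 - sqrt(1 - carrier_freq)`),
#' covariates, baseline clinical components, the non-response label from
#' `logistic(logit(baseline_nr_prob) + effect_log_or * carrier +
#' covariate effects)`, the responder split into moderate/good, and
#' month-6 clinical components by class-aware rejection sampling so that
#' the EULAR class recomputed from the components always equals the drawn
#' label.
#'
#' @param config a [sim_config()].
#' @return list with `visits` (two rows per patient), `covariates`,
#'   `genotypes` (`sample_id`, `deleted_allele_count`), and `labels`
#'   (response labels recomputed from the simulated components via
#'   [build_response_labels()], carrying the drawn class in
#'   `drawn_class`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))

  q <- 1 - sqrt(1 - config$causal_carrier_freq)
  allele <- stats::rbinom(n, 2, q)
  carrier <- as.integer(allele >= 1)

  bmi <- round(stats::rnorm(n, 23.5, 3.3), 1)
  bmi <- pmin(pmax(bmi, 15), 40)
  sex <- stats::rbinom(n, 1, 0.82)
  drug <- sample(names(config$drug_props), n, replace = TRUE,
                 prob = config$drug_props)
  mtx <- stats::rbinom(n, 1, 0.80)
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
  if (config$n_pcs > 0) colnames(pcs) <- paste0("pc", seq_len(config$n_pcs))

  base <- draw_components(n, "baseline")
  das_b <- das28_esr(base$tjc28, base$sjc28, base$esr, base$gh)

  ce <- config$covariate_effects
  lp <- stats::qlogis(config$baseline_nr_prob) +
    config$effect_log_or * carrier +
    ce$bmi * (bmi - 23.5) + ce$sex * sex + ce$mtx * mtx +
    ce$das28 * (das_b - 6.24) + ce$drug[drug]
  if (config$n_pcs > 0) lp <- lp + drop(pcs %*% rep(ce$pc, config$n_pcs))
  nr <- stats::rbinom(n, 1, stats::plogis(lp))

  cls <- ifelse(nr == 1, "none",
                ifelse(stats::runif(n) < config$moderate_frac,
                       "moderate", "good"))
  # a good response (attained <= 3.2 with improvement > 1.2) is only
  # reachable from baseline DAS28 > 4.4; a moderate response needs an
  # improvement > 0.6, impossible from a near-remission baseline
  cls[cls == "good" & das_b <= 4.45] <- "moderate"
  cls[cls == "moderate" & das_b <= 0.65] <- "none"

  m6 <- draw_month6(base, das_b, cls)

  visits <- rbind(
    data.frame(sample_id = ids, visit = "baseline", base,
               stringsAsFactors = FALSE),
    data.frame(sample_id = ids, visit = "month6", m6,
               stringsAsFactors = FALSE))
  visits <- visits[order(visits$sample_id, visits$visit), ]
  rownames(visits) <- NULL

  covariates <- data.frame(sample_id = ids, bmi = bmi, sex = sex,
                           drug = drug, mtx = mtx, pcs,
                           stringsAsFactors = FALSE)
  genotypes <- data.frame(sample_id = ids, deleted_allele_count = allele,
                          stringsAsFactors = FALSE)
  labels <- build_response_labels(visits)
  labels <- labels[match(ids, labels$sample_id), ]
  rownames(labels) <- NULL
  labels$drawn_class <- cls
  list(visits = visits, covariates = covariates, genotypes = genotypes,
       labels = labels)
}

clampi <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

# Baseline clinical components centred on an active-disease cohort
# (DAS28 about 6.2, CDAI about 34).
draw_components <- function(n, what) {
  stopifnot(what == "baseline")
  data.frame(tjc28 = clampi(stats::rnorm(n, 12, 4.5), 0, 28),
             sjc28 = clampi(stats::rnorm(n, 10, 4.0), 0, 28),
             esr = pmax(1, round(stats::rlnorm(n, log(40), 0.45))),
             gh = clampi(stats::rnorm(n, 60, 15), 0, 100),
             ptga = clampi(stats::rnorm(n, 6, 1.8), 0, 10),
             phga = clampi(stats::rnorm(n, 6, 1.8), 0, 10))
}

# Class-aware proposal for month-6 components. The proposal only shapes
# efficiency: every draw is re-classified with eular_response() and kept
# only if the class matches, so label/score consistency is guaranteed.
propose_month6 <- function(base, cls) {
  n <- nrow(base)
  out <- base
  none <- cls == "none"; good <- cls == "good"; mod <- cls == "moderate"
  k <- sum(none)
  if (k) {
    out$tjc28[none] <- clampi(base$tjc28[none] + stats::rnorm(k, 0, 2), 0, 28)
    out$sjc28[none] <- clampi(base$sjc28[none] + stats::rnorm(k, 0, 2), 0, 28)
    out$esr[none] <- pmax(1, round(base$esr[none] *
                                     exp(stats::rnorm(k, 0, 0.15))))
    out$gh[none] <- clampi(base$gh[none] + stats::rnorm(k, 0, 8), 0, 100)
    out$ptga[none] <- clampi(base$ptga[none] + stats::rnorm(k, 0, 1), 0, 10)
    out$phga[none] <- clampi(base$phga[none] + stats::rnorm(k, 0, 1), 0, 10)
  }
  k <- sum(good)
  if (k) {
    out$tjc28[good] <- clampi(stats::rnorm(k, 1, 1.2), 0, 28)
    out$sjc28[good] <- clampi(stats::rnorm(k, 1, 1.2), 0, 28)
    out$esr[good] <- pmax(1, round(stats::rlnorm(k, log(12), 0.4)))
    out$gh[good] <- clampi(stats::rnorm(k, 20, 8), 0, 100)
    out$ptga[good] <- clampi(stats::rnorm(k, 1.5, 1), 0, 10)
    out$phga[good] <- clampi(stats::rnorm(k, 1.5, 1), 0, 10)
  }
  k <- sum(mod)
  if (k) {
    out$tjc28[mod] <- clampi(stats::rnorm(k, 5, 2.5), 0, 28)
    out$sjc28[mod] <- clampi(stats::rnorm(k, 4, 2.0), 0, 28)
    out$esr[mod] <- pmax(1, round(stats::rlnorm(k, log(25), 0.4)))
    out$gh[mod] <- clampi(stats::rnorm(k, 40, 12), 0, 100)
    out$ptga[mod] <- clampi(stats::rnorm(k, 3.5, 1.5), 0, 10)
    out$phga[mod] <- clampi(stats::rnorm(k, 3.5, 1.5), 0, 10)
  }
  out
}

# Fallback proposal for atypical baselines: draw a target attained DAS28
# uniformly inside the class's feasible window, then build components whose
# four DAS28 terms split that target (random weights, rounded to legal
# integer grids).
propose_targeted <- function(das_b, cls) {
  n <- length(das_b)
  lo <- hi <- numeric(n)
  good <- cls == "good"; mod <- cls == "moderate"; none <- cls == "none"
  lo[good] <- 0; hi[good] <- pmin(3.2, das_b[good] - 1.21)
  hi_b2 <- pmin(das_b - 0.61, 5.1)        # moderate, 0.6 < delta <= 1.2 arm
  lo[mod] <- pmax(0, das_b[mod] - 1.19)
  hi[mod] <- hi_b2[mod]
  deep <- mod & das_b > 6.28              # only the delta > 1.2 arm remains
  lo[deep] <- 3.21; hi[deep] <- das_b[deep] - 1.21
  lo[none] <- pmax(0, das_b[none] - 0.59); hi[none] <- das_b[none] + 1.5
  t <- stats::runif(n, lo, pmax(lo, hi))
  w <- matrix(stats::rgamma(4 * n, shape = c(3, 1.5, 4, 1.5)), n, 4,
              byrow = TRUE)
  w <- w / rowSums(w)
  data.frame(
    tjc28 = clampi((w[, 1] * t / 0.56)^2, 0, 28),
    sjc28 = clampi((w[, 2] * t / 0.28)^2, 0, 28),
    esr = clampi(exp(w[, 3] * t / 0.70), 1, 300),
    gh = clampi(w[, 4] * t / 0.014, 0, 100),
    ptga = clampi(stats::rnorm(n, t, 0.8), 0, 10),
    phga = clampi(stats::rnorm(n, t, 0.8), 0, 10))
}

draw_month6 <- function(base, das_b, cls, maxit = 2000L, switch_at = 25L) {
  n <- nrow(base)
  out <- propose_month6(base, cls)
  pending <- eular_response(das_b, das28_esr(out$tjc28, out$sjc28,
                                             out$esr, out$gh)) != cls
  it <- 0L
  while (any(pending)) {
    it <- it + 1L
    if (it > maxit)
      stop("rejection sampling of month-6 components did not converge")
    prop <- if (it <= switch_at)
      propose_month6(base[pending, , drop = FALSE], cls[pending])
    else
      propose_targeted(das_b[pending], cls[pending])
    got <- eular_response(das_b[pending],
                          das28_esr(prop$tjc28, prop$sjc28,
                                    prop$esr, prop$gh)) == cls[pending]
    idx <- which(pending)[got]
    out[idx, ] <- prop[got, , drop = FALSE]
    pending[idx] <- FALSE
  }
  out
}

#' Simulate CNV calls consistent with the true genotypes
#'
#' Every causal-locus carrier receives a deletion call over the causal
#' region (copy number `2 - deleted_allele_count`) with endpoints jittered
#' by rounded Normal(0, `boundary_jitter_sd`) noise, truncated so the call
#' still overlaps the region. Background CNVs (Poisson count per sample,
#' copy number from 0/1/3/4, length log-normal around 20 kb) are placed
#' uniformly on `genome_map` and, by default, never overlap the causal
#' region or each other within a sample. Every call has at least 4
#' supporting probes.
#'
#' @param genotypes data.frame from [simulate_cohort()].
#' @param config a [sim_config()].
#' @param genome_map data.frame (`chromosome`, `length`) for background
#'   placement; default [default_genome_map()].
#' @return calls data.frame as produced by the caller.
#' @export
simulate_cnv_calls <- function(genotypes, config,
                               genome_map = default_genome_map()) {
  stopifnot(inherits(config, "sim_config"))
  if (!nrow(genotypes)) stop("genotypes must be nonempty")
  set.seed(config$seed + 1L)
  reg <- config$causal_region
  carriers <- genotypes[genotypes$deleted_allele_count >= 1, , drop = FALSE]

  causal <- NULL
  if (nrow(carriers)) {
    k <- nrow(carriers)
    s <- reg$start + round(stats::rnorm(k, 0, config$boundary_jitter_sd))
    e <- reg$end + round(stats::rnorm(k, 0, config$boundary_jitter_sd))
    s <- pmin(pmax(s, 1), reg$end - 1)  # keep overlap with the region
    e <- pmax(e, pmax(s + 1, reg$start + 1))
    causal <- empty_calls(
      sample_id = carriers$sample_id,
      chromosome = rep(reg$chromosome, k),
      start = s, end = e,
      copy_number = 2L - pmin(carriers$deleted_allele_count, 2L),
      num_snps = rep(5L, k),
      start_probe = sprintf("rs_causal_start_%d", seq_len(k)),
      end_probe = sprintf("rs_causal_end_%d", seq_len(k)))
  }

  bg <- list()
  if (config$background_cnv_rate > 0) {
    counts <- stats::rpois(nrow(genotypes), config$background_cnv_rate)
    for (i in which(counts > 0)) {
      m <- counts[i]
      chrom <- sample(genome_map$chromosome, m, replace = TRUE)
      len <- pmax(1000, round(stats::rlnorm(m, log(2e4), 0.8)))
      maxpos <- genome_map$length[match(chrom, genome_map$chromosome)]
      st <- floor(stats::runif(m, 1, pmax(2, maxpos - len)))
      en <- st + len - 1
      cn <- sample(c(0L, 1L, 3L, 4L), m, replace = TRUE,
                   prob = c(0.05, 0.60, 0.30, 0.05))
      d <- empty_calls(sample_id = rep(genotypes$sample_id[i], m),
                       chromosome = chrom, start = st, end = en,
                       copy_number = cn,
                       num_snps = 4L + stats::rpois(m, 6),
                       start_probe = sprintf("rs_bg_%d_%d_s", i, seq_len(m)),
                       end_probe = sprintf("rs_bg_%d_%d_e", i, seq_len(m)))
      # avoid the causal region and within-sample overlaps
      d <- d[!(d$chromosome == reg$chromosome &
                 d$start <= reg$end & d$end >= reg$start), , drop = FALSE]
      if (nrow(d) > 1) {
        o <- order(d$chromosome, d$start)
        d <- d[o, ]
        ovl <- c(FALSE, d$chromosome[-1] == d$chromosome[-nrow(d)] &
                   d$start[-1] <= d$end[-nrow(d)])
        d <- d[!ovl, , drop = FALSE]
      }
      bg[[length(bg) + 1L]] <- d
    }
  }
  out <- do.call(rbind, c(list(causal), bg, list(empty_calls()),
                          make.row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Simulate probe-level LRR/BAF signal from CNV calls
#'
#' The generative converse of the caller's emission model: at each probe
#' the local copy number is 2 unless a call of the sample covers it; LRR
#' is Normal(state mean, `noise_sd`) and BAF is drawn from the copy-number
#' specific cluster mixture, with the allelic composition sampled at the
#' probe's population B-allele frequency. With `noise_sd = 0` and zero
#' cluster SDs the emission means are returned exactly.
#'
#' @param calls calls data.frame (may be empty).
#' @param probe_map data.frame (`name`, `chromosome`, `position`, `pfb`)
#'   sorted by (chromosome, position).
#' @param noise_sd LRR noise SD.
#' @param seed integer seed.
#' @param sample_ids samples to emit signal for; defaults to the samples
#'   in `calls`.
#' @param model [hmm_model()] providing the emission means and BAF cluster
#'   SDs.
#' @return data.frame with `sample_id`, `probe`, `chromosome`, `position`,
#'   `lrr`, `baf`.
#' @export
simulate_signal <- function(calls, probe_map, noise_sd = 0.15, seed = 1,
                            sample_ids = unique(calls$sample_id),
                            model = hmm_model()) {
  ord <- order(probe_map$chromosome, probe_map$position)
  if (!identical(ord, seq_len(nrow(probe_map))))
    stop("probe_map must be sorted by (chromosome, position)")
  if (any(probe_map$pfb < 0 | probe_map$pfb > 1))
    stop("probe pfb must be in [0, 1]")
  if (any(duplicated(probe_map[, c("chromosome", "position")])))
    stop("probe_map has duplicated positions")
  set.seed(seed)
  np <- nrow(probe_map)
  out <- vector("list", length(sample_ids))
  for (i in seq_along(sample_ids)) {
    sid <- sample_ids[i]
    cn <- rep(2L, np)
    cc <- calls[calls$sample_id == sid, , drop = FALSE]
    for (k in seq_len(nrow(cc))) {
      hit <- probe_map$chromosome == cc$chromosome[k] &
        probe_map$position >= cc$start[k] & probe_map$position <= cc$end[k]
      cn[hit] <- cc$copy_number[k]
    }
    lrr <- stats::rnorm(np, model$lrr_means[cn + 1L], noise_sd)
    nb <- ifelse(cn > 0, stats::rbinom(np, pmax(cn, 1), probe_map$pfb), 0L)
    mu <- ifelse(cn > 0, nb / pmax(cn, 1), 0.5)
    sd_b <- ifelse(mu %in% c(0, 1), model$baf_boundary_sd, model$baf_sd)
    if (noise_sd == 0) sd_b <- 0  # noiseless limit: exact emission means
    baf <- ifelse(cn == 0, stats::runif(np),
                  pmin(pmax(stats::rnorm(np, mu, sd_b), 0), 1))
    out[[i]] <- data.frame(sample_id = sid, probe = probe_map$name,
                           chromosome = probe_map$chromosome,
                           position = probe_map$position,
                           lrr = lrr, baf = baf, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
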