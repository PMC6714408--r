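#' Maximum-likelihood logistic regression with a Firth fallback
#'
#' Fits a binary-outcome logistic model by iteratively reweighted least
#' squares. When the fit shows quasi-separation (a fitted probability
#' within 1e-8 of 0 or 1 together with a diverging coefficient, or
#' non-convergence), the model is refitted with Firth's penalized
#' likelihood, which keeps rare-carrier estimates finite.
#'
#' @param y binary outcome vector (0/1).
#' @param design numeric design matrix including the intercept column;
#'   must be full rank.
#' @return list with `beta`, `se`, `z`, `p` (Wald), `vcov`, `converged`,
#'   `separation` (logical flag), and `method` (`"mle"` or `"firth"`).
#' @examples
#' y <- rep(c(0, 1), c(30, 10))
#' fit_logistic(y, cbind(intercept = rep(1, 40)))$beta  # log(10/30)
#' @export
fit_logistic <- function(y, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (nrow(design) <= ncol(design))
    stop("more predictors than observations")
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[-qr_d$pivot[seq_len(qr_d$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(design, y, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100)))
  mu <- fit$fitted.values
  sep <- (any(mu < 1e-8 | mu > 1 - 1e-8) &&
            max(abs(fit$coefficients)) > 10) || !fit$converged
  if (sep) {
    f <- firth_logistic(y, design)
    return(list(beta = f$beta, se = f$se, z = f$beta / f$se,
                p = 2 * stats::pnorm(-abs(f$beta / f$se)),
                vcov = f$vcov, converged = f$converged,
                separation = TRUE, method = "firth"))
  }
  w <- mu * (1 - mu)
  info <- crossprod(design * w, design)
  vc <- solve(info)
  se <- sqrt(diag(vc))
  beta <- fit$coefficients
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       vcov = vc, converged = fit$converged, separation = FALSE,
       method = "mle")
}

# Firth's bias-reduced logistic regression: Newton iterations on the
# modified score U*(b) = X'(y - mu + h (1/2 - mu)), h the hat diagonals.
firth_logistic <- function(y, X, maxit = 200L, tol = 1e-9) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(X * w, X)
    inv <- solve(info)
    h <- rowSums((X %*% inv) * X) * w
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    delta <- drop(inv %*% U)
    # step-halving for stability
    step <- 1
    while (max(abs(step * delta)) > 5) step <- step / 2
    beta <- beta + step * delta
    if (max(abs(step * delta)) < tol) { converged <- TRUE; break }
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  vc <- solve(crossprod(X * w, X))
  list(beta = stats::setNames(drop(beta), colnames(X)),
       se = sqrt(diag(vc)), vcov = vc, converged = converged)
}

# Covariate design shared by both association models: PCs, BMI, sex,
# reference-coded drug (reference = etanercept), MTX.
covariate_design <- function(covariates, drug_reference = "etanercept") {
  pcs <- as.matrix(covariates[, grep("^pc", names(covariates)), drop = FALSE])
  drug <- factor(covariates$drug)
  if (drug_reference %in% levels(drug))
    drug <- stats::relevel(drug, ref = drug_reference)
  dd <- if (nlevels(drug) > 1) {
    m <- stats::model.matrix(~drug)[, -1, drop = FALSE]
    colnames(m) <- sub("^drug", "drug_", colnames(m))
    m
  } else NULL
  cbind(bmi = covariates$bmi, sex = covariates$sex, mtx = covariates$mtx,
        dd, pcs)
}

#' Logistic association of one CNV segment with EULAR non-response
#'
#' Outcome 1 = EULAR class `none` (non-responder). The genetic predictor
#' is the deletion-carrier indicator (copy number <= 1); duplication
#' carriers sit in the reference class. Covariates: genetic principal
#' components, BMI, sex, baseline DAS28, TNF-alpha blocker (reference
#' etanercept), and methotrexate use.
#'
#' @param cn_column integer copy numbers of all samples at the segment,
#'   ordered like `labels$sample_id`.
#' @param labels response labels from [build_response_labels()].
#' @param covariates covariate data.frame (`sample_id`, `bmi`, `sex`,
#'   `drug`, `mtx`, `pc1`..`pcK`) aligned to `labels`.
#' @param segment_id identifier stamped on the result.
#' @param adjusted include covariates (default TRUE); FALSE gives the
#'   crude single-predictor model.
#' @return one-row data.frame: `segment_id`, `coding`, `beta`, `se`,
#'   `or_`, `ci_low`, `ci_high`, `p_value`, `method`, `model`.
#' @export
assoc_segment_logistic <- function(cn_column, labels, covariates,
                                   segment_id = "segment", adjusted = TRUE) {
  stopifnot(length(cn_column) == nrow(labels))
  y <- as.integer(labels$eular_class == "none")
  carrier <- as.integer(cn_column <= 1L)
  if (all(carrier == 0L) || all(carrier == 1L))
    stop("degenerate predictor: deletion-carrier indicator is constant")
  X <- cbind(intercept = 1, carrier = carrier)
  if (adjusted) {
    stopifnot(identical(labels$sample_id, covariates$sample_id))
    X <- cbind(X, baseline_das28 = labels$das28_baseline,
               covariate_design(covariates))
  }
  fit <- fit_logistic(y, X)
  assoc_row(segment_id, fit$beta["carrier"], fit$se["carrier"],
            fit$p["carrier"], fit$method, "logistic_eular", exp_scale = TRUE)
}

#' Linear association of one CNV segment with the change in CDAI
#'
#' Ordinary least squares of the CDAI change on the deletion-carrier
#' indicator, baseline CDAI and the shared covariates (no baseline DAS28).
#' The default outcome orientation is improvement
#' (`baseline - month6`); `orientation = "worsening"` negates it, which
#' flips the sign of the coefficient but leaves the p-value unchanged.
#'
#' @inheritParams assoc_segment_logistic
#' @param orientation `"improvement"` (default) or `"worsening"`.
#' @return one-row data.frame as in [assoc_segment_logistic()] with
#'   `model = "linear_cdai"`; `or_`, `ci_low`, `ci_high` are on the beta
#'   scale.
#' @export
assoc_segment_linear <- function(cn_column, labels, covariates,
                                 segment_id = "segment",
                                 orientation = c("improvement", "worsening"),
                                 adjusted = TRUE) {
  orientation <- match.arg(orientation)
  stopifnot(length(cn_column) == nrow(labels))
  yy <- labels$delta_cdai
  if (orientation == "worsening") yy <- -yy
  carrier <- as.integer(cn_column <= 1L)
  if (all(carrier == 0L) || all(carrier == 1L))
    stop("degenerate predictor: deletion-carrier indicator is constant")
  X <- cbind(intercept = 1, carrier = carrier)
  if (adjusted) {
    stopifnot(identical(labels$sample_id, covariates$sample_id))
    X <- cbind(X, baseline_cdai = labels$cdai_baseline,
               covariate_design(covariates))
  }
  fit <- stats::lm.fit(X, yy)
  rss <- sum(fit$residuals^2)
  df <- length(yy) - fit$rank
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  b <- fit$coefficients["carrier"]
  tval <- b / se["carrier"]
  p <- 2 * stats::pt(-abs(tval), df)
  out <- assoc_row(segment_id, b, se["carrier"], p, "ols", "linear_cdai",
                   exp_scale = FALSE)
  out
}

assoc_row <- function(segment_id, beta, se, p, method, model, exp_scale) {
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  est <- if (exp_scale) exp(c(beta, ci)) else c(beta, ci)
  data.frame(segment_id = segment_id, coding = "deletion_carrier",
             beta = unname(beta), se = unname(se),
             or_ = unname(est[1]), ci_low = unname(est[2]),
             ci_high = unname(est[3]),
             p_value = unname(max(p, .Machine$double.xmin)),
             method = method, model = model,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: p-values are ranked, the largest rank `i` with
#' `p(i) <= i q / m` is found, and all smaller p-values are declared
#' significant. Adjusted values are the usual monotone
#' `min over j >= i of m p(j) / j`.
#'
#' @param p_values vector of p-values in (0, 1].
#' @param q target false discovery rate (default 0.05).
#' @return list with `significant` (logical) and `adjusted` (BH-adjusted
#'   p-values).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p_values must lie in (0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(significant = adj <= q, adjusted = adj)
}

#' Crude odds ratio from a 2x2 table with Woolf confidence interval
#'
#' `OR = (n11 n00) / (n10 n01)` with the 95% Woolf interval
#' `exp(ln OR +/- 1.96 sqrt(sum 1/n))`. When any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and
#' flagged.
#'
#' @param n11 exposed cases.
#' @param n10 exposed controls.
#' @param n01 unexposed cases.
#' @param n00 unexposed controls.
#' @return list with `or_`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' crude_or(7, 13, 25, 312)$or_  # 6.72: carriers among non-responders
#' @export
crude_or <- function(n11, n10, n01, n00) {
  stopifnot(n11 >= 0, n10 >= 0, n01 >= 0, n00 >= 0)
  cells <- c(n11, n10, n01, n00)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or_ <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or_) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(or_ = or_, ci_low = ci[1], ci_high = ci[2], corrected = corrected)
}

#' SNP tagging of a CNV: squared correlation between dosages
#'
#' For each SNP (optionally restricted to a window around the segment),
#' reports the squared Pearson correlation between the SNP allele dosage
#' (0/1/2) and the deletion dosage (0/1/2). Monomorphic SNPs are reported
#' as r2 = 0 with a flag.
#'
#' @param snp_dosage matrix (samples x SNPs) or vector of dosages in
#'   0/1/2.
#' @param deletion_dosage vector of deletion-allele dosages (0/1/2),
#'   aligned by sample.
#' @param snp_positions optional bp positions of the SNPs.
#' @param segment optional list/row with `start` and `end`; with
#'   `snp_positions`, restricts to SNPs within `window` of the segment.
#' @param window half-width of the tagging window in bp (default 1 Mb).
#' @return data.frame with `snp`, `r2`, `monomorphic`, plus attribute
#'   `max_r2`.
#' @export
snp_cnv_r2 <- function(snp_dosage, deletion_dosage, snp_positions = NULL,
                       segment = NULL, window = 1e6) {
  m <- as.matrix(snp_dosage)
  if (is.null(colnames(m))) colnames(m) <- paste0("snp", seq_len(ncol(m)))
  stopifnot(nrow(m) == length(deletion_dosage))
  keep <- rep(TRUE, ncol(m))
  if (!is.null(snp_positions) && !is.null(segment))
    keep <- snp_positions >= segment$start - window &
      snp_positions <= segment$end + window
  m <- m[, keep, drop = FALSE]
  mono <- apply(m, 2, function(x) stats::var(x) == 0)
  r2 <- rep(0, ncol(m))
  if (stats::var(deletion_dosage) > 0 && any(!mono))
    r2[!mono] <- drop(stats::cor(m[, !mono, drop = FALSE],
                                 deletion_dosage))^2
  out <- data.frame(snp = colnames(m), r2 = r2, monomorphic = mono,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "max_r2") <- if (nrow(out)) max(out$r2) else NA_real_
  out
}

#' Test every segment of a segment matrix against drug response
#'
#' Runs [assoc_segment_logistic()] (and/or [assoc_segment_linear()]) on
#' each segment and applies [bh_fdr()] across the tested segments of each
#' model. Segments whose deletion-carrier indicator is constant are
#' reported with `NA` estimates and excluded from the FDR.
#'
#' @param sm a (typically filtered) `segment_matrix`.
#' @param labels,covariates as in [assoc_segment_logistic()]; rows must be
#'   ordered like `sm$sample_ids`.
#' @param models character subset of `c("logistic_eular", "linear_cdai")`.
#' @param fdr_q FDR threshold (default 0.05).
#' @param orientation passed to [assoc_segment_linear()].
#' @return data.frame of association results with columns `q_value` and
#'   `fdr_significant` appended.
#' @export
assoc_all_segments <- function(sm, labels, covariates,
                               models = c("logistic_eular", "linear_cdai"),
                               fdr_q = 0.05,
                               orientation = "improvement") {
  stopifnot(inherits(sm, "segment_matrix"))
  stopifnot(identical(labels$sample_id, sm$sample_ids),
            identical(covariates$sample_id, sm$sample_ids))
  res <- list()
  for (model in models) {
    rows <- lapply(seq_len(nrow(sm$segments)), function(j) {
      sid <- sm$segments$segment_id[j]
      tryCatch({
        if (model == "logistic_eular")
          assoc_segment_logistic(sm$cn[, j], labels, covariates, sid)
        else
          assoc_segment_linear(sm$cn[, j], labels, covariates, sid,
                               orientation = orientation)
      }, error = function(e) {
        data.frame(segment_id = sid, coding = "deletion_carrier",
                   beta = NA_real_, se = NA_real_, or_ = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   p_value = NA_real_, method = "skipped", model = model,
                   stringsAsFactors = FALSE)
      })
    })
    tab <- do.call(rbind, rows)
    ok <- !is.na(tab$p_value)
    tab$q_value <- NA_real_
    tab$fdr_significant <- FALSE
    if (any(ok)) {
      fdr <- bh_fdr(tab$p_value[ok], fdr_q)
      tab$q_value[ok] <- fdr$adjusted
      tab$fdr_significant[ok] <- fdr$significant
    }
    res[[model]] <- tab
  }
  do.call(rbind, c(res, make.row.names = FALSE))
}
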