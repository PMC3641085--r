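# Two-stream GMM parentese detector: per-class GMMs on segmental (MFCC
# frames) and supra-segmental (prosodic statistics) features, combined by a
# convex posterior fusion with weight lambda.

norm_class <- function(x) {
  ifelse(x == "parentese", "parentese", "other_speech")
}

#' Fusion configuration of the two-stream detector
#'
#' Defaults follow the detector's most effective configuration: fusion weight
#' `lambda = 0.4` on the segmental stream, `M = 12` Gaussians for the
#' segmental GMMs and `M = 15` for the supra-segmental GMMs.
#'
#' @param lambda Fusion weight on the segmental stream, in `[0, 1]`.
#' @param m_segmental,m_suprasegmental Mixture sizes of the two streams.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(lambda = 0.4, m_segmental = 12L,
                          m_suprasegmental = 15L) {
  if (lambda < 0 || lambda > 1) abort("`lambda` must be in [0, 1].")
  structure(list(lambda = lambda, m_segmental = as.integer(m_segmental),
                 m_suprasegmental = as.integer(m_suprasegmental)),
            class = "fusion_config")
}

SUPRA_FEATURES <- c("f0_mean", "f0_sd", "f0_min", "f0_max", "f0_range",
                    "f0_slope", "energy_mean", "energy_sd", "energy_range",
                    "duration", "voiced_fraction")

#' Train the two-stream parentese detector
#'
#' Fits, per class (parentese vs other speech), one diagonal-covariance GMM on
#' the pooled mean-variance-normalised MFCC frames (segmental stream) and one
#' on the standardised prosodic statistics vectors (supra-segmental stream).
#' Utterances without voiced frames contribute only to the segmental stream.
#'
#' @param corpus A labelled corpus tibble from [synth_corpus()], or any tibble
#'   with a `style` column and an `utterance` list-column.
#' @param config A [fusion_config()].
#' @param seed Integer seed for the GMM initialisations.
#' @param verbose Print per-stream fitting progress.
#' @return Object of class `parentese_detector` holding the four GMMs, the
#'   feature scalers and the fusion configuration.
#' @export
train_parentese_detector <- function(corpus, config = fusion_config(),
                                     seed = 1L, verbose = FALSE) {
  stopifnot(all(c("style", "utterance") %in% names(corpus)))
  cls <- norm_class(corpus$style)
  if (length(unique(cls)) != 2) abort("corpus must contain both classes")

  seg <- map(corpus$utterance, function(u) extract_segmental(u)$features)
  supra <- map(corpus$utterance, function(u) {
    suppressWarnings(as.matrix(extract_suprasegmental(u)[, SUPRA_FEATURES]))
  })

  seg_all <- do.call(rbind, seg)
  seg_center <- colMeans(seg_all)
  seg_scale <- pmax(apply(seg_all, 2, stats::sd), 1e-8)

  supra_all <- do.call(rbind, supra)
  keep <- stats::complete.cases(supra_all)
  supra_center <- colMeans(supra_all[keep, , drop = FALSE])
  supra_scale <- pmax(apply(supra_all[keep, , drop = FALSE], 2, stats::sd), 1e-8)

  seeds <- derive_seeds(seed, 4L)
  models <- list()
  for (i in seq_along(classes <- c("parentese", "other_speech"))) {
    cl <- classes[i]
    in_cl <- cls == cl
    if (verbose) message("fitting segmental GMM for ", cl)
    seg_cl <- scale(do.call(rbind, seg[in_cl]), seg_center, seg_scale)
    models[[paste0("seg_", cl)]] <-
      fit_gmm(seg_cl, config$m_segmental, seed = seeds[i])
    if (verbose) message("fitting supra-segmental GMM for ", cl)
    sup_cl <- do.call(rbind, supra[in_cl])
    sup_cl <- sup_cl[stats::complete.cases(sup_cl), , drop = FALSE]
    sup_cl <- scale(sup_cl, supra_center, supra_scale)
    models[[paste0("supra_", cl)]] <-
      fit_gmm(sup_cl, config$m_suprasegmental, seed = seeds[i + 2])
  }

  structure(
    list(models = models, config = config,
         seg_center = seg_center, seg_scale = seg_scale,
         supra_center = supra_center, supra_scale = supra_scale),
    class = "parentese_detector"
  )
}

#' Per-stream, per-class scores for one utterance
#'
#' The segmental score is the duration-normalised mean per-frame
#' log-likelihood of the utterance's MFCC frames under the class model; the
#' supra-segmental score is the log-likelihood of the single prosodic
#' statistics vector. When an utterance has no voiced frames its
#' supra-segmental scores are set equal across classes (the class-prior
#' score), so the decision falls to the segmental stream alone.
#'
#' @param detector A trained [train_parentese_detector()] object.
#' @param x A single utterance (see [extract_segmental()] for accepted forms).
#' @return Tibble with columns `stream`, `class`, `score`.
#' @export
score_streams <- function(detector, x) {
  stopifnot(inherits(detector, "parentese_detector"))
  segf <- scale(extract_segmental(x)$features,
                detector$seg_center, detector$seg_scale)
  supv <- suppressWarnings(
    as.matrix(extract_suprasegmental(x)[, SUPRA_FEATURES])
  )
  no_voiced <- anyNA(supv)
  if (!no_voiced) {
    supv <- scale(supv, detector$supra_center, detector$supra_scale)
  }
  rows <- list()
  for (cl in c("parentese", "other_speech")) {
    rows[[length(rows) + 1L]] <- tibble(
      stream = "segmental", class = cl,
      score = mean(gmm_logdens(detector$models[[paste0("seg_", cl)]], segf))
    )
    sup_score <- if (no_voiced) 0 else
      gmm_logdens(detector$models[[paste0("supra_", cl)]], supv)
    rows[[length(rows) + 1L]] <- tibble(
      stream = "suprasegmental", class = cl, score = as.numeric(sup_score)
    )
  }
  if (no_voiced) {
    warn("no voiced frames: supra-segmental stream set to the class prior")
  }
  bind_rows(rows)
}

#' Fuse stream scores into a classification
#'
#' Each stream's class scores are converted to class posteriors by a softmax
#' over the two classes (uniform priors); the fused parentese posterior is the
#' convex combination `lambda * P_segmental + (1 - lambda) * P_suprasegmental`
#' and the label is the argmax, with exact ties resolved to `other_speech`.
#' `lambda = 1` reduces to the segmental-only classifier, `lambda = 0` to the
#' supra-segmental-only classifier.
#'
#' @param scores Tibble from [score_streams()] (columns `stream`, `class`,
#'   `score`).
#' @param lambda Fusion weight in `[0, 1]`.
#' @return One-row tibble: `label`, `posterior_parentese`, `p_segmental`,
#'   `p_suprasegmental`.
#' @examples
#' s <- tibble::tibble(
#'   stream = rep(c("segmental", "suprasegmental"), each = 2),
#'   class = rep(c("parentese", "other_speech"), 2),
#'   score = c(log(0.9), log(0.1), log(0.2), log(0.8))
#' )
#' fuse_and_classify(s, lambda = 0.4)
#' @export
fuse_and_classify <- function(scores, lambda = 0.4) {
  if (lambda < 0 || lambda > 1) abort("`lambda` must be in [0, 1].")
  post <- function(stream) {
    s <- scores[scores$stream == stream, ]
    if (nrow(s) != 2) abort(paste0("need scores for both classes in ", stream))
    sp <- s$score[s$class == "parentese"]
    so <- s$score[s$class == "other_speech"]
    1 / (1 + exp(so - sp))  # softmax over two classes
  }
  p_seg <- post("segmental")
  p_sup <- post("suprasegmental")
  p <- lambda * p_seg + (1 - lambda) * p_sup
  tibble(
    label = if (p > 0.5) "parentese" else "other_speech",
    posterior_parentese = p, p_segmental = p_seg, p_suprasegmental = p_sup
  )
}

#' Classify a corpus with a trained detector
#'
#' @param object A `parentese_detector`.
#' @param newdata Corpus tibble with an `utterance` list-column.
#' @param lambda Fusion weight; defaults to the detector's configuration.
#' @param ... Unused.
#' @return The corpus tibble without the waveforms, plus `.pred_class` and
#'   `posterior_parentese`.
#' @export
predict.parentese_detector <- function(object, newdata,
                                       lambda = object$config$lambda, ...) {
  res <- map(newdata$utterance, function(u) {
    fuse_and_classify(score_streams(object, u), lambda = lambda)
  }) |> list_rbind()
  out <- newdata[, setdiff(names(newdata), "utterance")]
  out$.pred_class <- res$label
  out$posterior_parentese <- res$posterior_parentese
  out$p_segmental <- res$p_segmental
  out$p_suprasegmental <- res$p_suprasegmental
  out
}

#' @export
print.parentese_detector <- function(x, ...) {
  cat(sprintf(
    "<parentese_detector> lambda=%.2f  M(segmental)=%d  M(supra-segmental)=%d\n",
    x$config$lambda, x$config$m_segmental, x$config$m_suprasegmental
  ))
  invisible(x)
}

#' Evaluate binary classification with exact binomial confidence intervals
#'
#' Confusion counts and the three headline metrics of a binary detector —
#' accuracy `(TP+TN)/n`, positive predictive value `TP/(TP+FP)` and negative
#' predictive value `TN/(TN+FN)` — each with a two-sided exact
#' (Clopper-Pearson) 95% binomial confidence interval on its own
#' numerator/denominator pair. A metric with a zero denominator is reported
#' as missing with its interval omitted.
#'
#' @param truth,estimate Equal-length label vectors; any label other than
#'   `positive` is treated as the negative class.
#' @param positive The positive-class label (default `"parentese"`).
#' @param conf_level Confidence level of the exact intervals.
#' @return Object of class `eval_report`: confusion counts and a metric table
#'   in percent.
#' @examples
#' evaluate_classifier(rep(c("parentese", "other_speech"), c(50, 50)),
#'                     rep(c("parentese", "other_speech", "parentese",
#'                           "other_speech"), c(40, 10, 16, 34)))
#' @export
evaluate_classifier <- function(truth, estimate, positive = "parentese",
                                conf_level = 0.95) {
  if (length(truth) != length(estimate)) abort("length mismatch")
  if (length(truth) == 0) abort("empty input")
  t_pos <- truth == positive
  e_pos <- estimate == positive
  tp <- sum(t_pos & e_pos); fn <- sum(t_pos & !e_pos)
  fp <- sum(!t_pos & e_pos); tn <- sum(!t_pos & !e_pos)

  one <- function(metric, k, n) {
    if (n == 0) {
      return(tibble(metric = metric, successes = NA_integer_,
                    trials = 0L, value = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_))
    }
    ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
    tibble(metric = metric, successes = as.integer(k), trials = as.integer(n),
           value = 100 * k / n, ci_lower = 100 * ci[1], ci_upper = 100 * ci[2])
  }
  metrics <- bind_rows(
    one("accuracy", tp + tn, tp + tn + fp + fn),
    one("ppv", tp, tp + fp),
    one("npv", tn, tn + fn)
  )
  structure(
    list(counts = c(tp = tp, fn = fn, fp = fp, tn = tn),
         metrics = metrics, positive = positive, conf_level = conf_level),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  (TP=%d FN=%d FP=%d TN=%d; positive=%s)\n",
              sum(x$counts), x$counts["tp"], x$counts["fn"], x$counts["fp"],
              x$counts["tn"], x$positive))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$value[i])) {
      cat(sprintf("  %-9s undefined (zero denominator)\n", m$metric[i]))
    } else {
      cat(sprintf("  %-9s %6.2f%%  (%d%% CI %.2f-%.2f%%)\n", m$metric[i],
                  m$value[i], round(100 * x$conf_level), m$ci_lower[i],
                  m$ci_upper[i]))
    }
  }
  invisible(x)
}

#' @rdname evaluate_classifier
#' @param x An `eval_report`.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$metrics
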