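# IBD detection-error model: false positives, length-dependent recall,
# Gaussian length noise; the rate-correction convolution used inside the
# likelihood; error injection into ground-truth segments.

#' Construct an IBD detection-error model
#'
#' @param fp false-positive density per haplotype pair per cM: a function of
#'   length in cM, or a single number (constant).
#' @param recall detection probability as a function of true length in cM, or
#'   a single number in `[0, 1]`.
#' @param sigma_cm standard deviation of the Gaussian length noise in cM
#'   (default 1.5; 0 means lengths are reported exactly).
#' @param window_cm half-width of the truncated convolution window in cM
#'   (default 5; the kernel is truncated, not renormalized, losing ~0.3% of
#'   its mass at 5 cM = 3.33 sigma).
#' @param step_cm discretization step of the convolution (default 0.25).
#' @param fp_total_morgan total genetic map length (Morgans) the fp density
#'   refers to; when set, fp is rescaled proportionally on chromosome subsets
#'   (cross-validation folds, bootstrap replicates). `NULL` disables scaling.
#' @return object of class `ibd_error_model`.
#' @export
error_model <- function(fp, recall, sigma_cm = 1.5, window_cm = 5,
                        step_cm = 0.25, fp_total_morgan = NULL) {
  if (sigma_cm < 0 || window_cm <= 0 || step_cm <= 0)
    stop_domain("sigma must be >= 0; window and step > 0")
  as_fun <- function(f, what, lo = 0, hi = Inf) {
    if (is.function(f)) return(f)
    if (is.numeric(f) && length(f) == 1L) {
      if (f < lo || f > hi) stop_domain(what, " out of range")
      force(f); return(function(l) rep(f, length(l)))
    }
    stop_domain(what, " must be a function or a single number")
  }
  structure(list(fp = as_fun(fp, "fp"), recall = as_fun(recall, "recall", 0, 1),
                 sigma_cm = sigma_cm, window_cm = window_cm, step_cm = step_cm,
                 fp_total_morgan = fp_total_morgan),
            class = "ibd_error_model")
}

#' Identity error model (no detection errors)
#'
#' FP = 0, recall = 1, no length noise; the corrected rate equals the
#' theoretical rate and [inject_errors()] returns its input unchanged.
#' @inheritParams error_model
#' @return an [error_model()].
#' @export
identity_error_model <- function(window_cm = 5, step_cm = 0.25) {
  error_model(fp = 0, recall = 1, sigma_cm = 0, window_cm = window_cm,
              step_cm = step_cm)
}

#' Default simulation error model
#'
#' The error model used in the error-injection experiments: false positives at
#' the genome-wide sharing rate of a constant population of size `ne_fp`
#' (default 25,000), the parametric recall curve, and Gaussian length noise
#' with sd 1.5 cM.
#'
#' @param chrom_map the [chromosome_map()] over which FP sharing is summed.
#' @param ne_fp constant Ne whose sharing rate defines the FP density.
#' @inheritParams error_model
#' @return an [error_model()].
#' @export
default_error_model <- function(chrom_map, ne_fp = 25000, sigma_cm = 1.5,
                                window_cm = 5, step_cm = 0.25) {
  force(chrom_map); force(ne_fp)
  error_model(fp = function(l) default_fp_density(l, chrom_map, ne_fp),
              recall = parametric_recall, sigma_cm = sigma_cm,
              window_cm = window_cm, step_cm = step_cm,
              fp_total_morgan = sum(chrom_map))
}

#' Read an error model from a tab-separated table
#'
#' Expected columns: `bin_midpoint_cm`, `fp_density_per_pair_per_cm`,
#' `recall`. FP and recall are interpolated linearly (constant beyond the
#' table range).
#'
#' @param path file path.
#' @inheritParams error_model
#' @return an [error_model()].
#' @export
read_error_model <- function(path, sigma_cm = 1.5, window_cm = 5,
                             step_cm = 0.25, fp_total_morgan = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("bin_midpoint_cm", "fp_density_per_pair_per_cm", "recall")
  if (!all(req %in% names(tab)))
    stop_domain("error-model table must have columns: ", paste(req, collapse = ", "))
  if (any(tab$recall < 0 | tab$recall > 1)) stop_domain("recall must be in [0, 1]")
  if (any(tab$fp_density_per_pair_per_cm < 0)) stop_domain("fp density must be >= 0")
  fp <- stats::approxfun(tab$bin_midpoint_cm, tab$fp_density_per_pair_per_cm, rule = 2)
  rc <- stats::approxfun(tab$bin_midpoint_cm, tab$recall, rule = 2)
  error_model(fp = fp, recall = rc, sigma_cm = sigma_cm, window_cm = window_cm,
              step_cm = step_cm, fp_total_morgan = fp_total_morgan)
}

#' Parametric recall curve
#'
#' `recall(l) = 1 - 1 / (1 + 0.025 l exp(0.25 l))` with `l` in cM: 0 at
#' `l = 0`, monotone increasing, approaching 1 for long segments. The
#' functional form used when simulating limited detection power.
#'
#' @param l_cm segment length(s) in cM (>= 0).
#' @return detection probability in `[0, 1)`.
#' @export
parametric_recall <- function(l_cm) {
  if (any(l_cm < 0)) stop_domain("length must be >= 0")
  1 - 1 / (1 + 0.025 * l_cm * exp(0.25 * l_cm))
}

#' Default false-positive density
#'
#' The expected genome-wide IBD sharing density (per haplotype pair per cM) of
#' a constant population of size `ne_fp` (default 25,000) under the closed
#' form, summed over the chromosome map. Serves as the false-positive rate in
#' error-injection experiments.
#'
#' @param l_cm length(s) in cM (> 0).
#' @param chrom_map a [chromosome_map()].
#' @param ne_fp constant diploid effective size.
#' @return density per pair per cM (vectorized over `l_cm`).
#' @export
default_fp_density <- function(l_cm, chrom_map, ne_fp = 25000) {
  if (any(l_cm <= 0)) stop_domain("length must be > 0")
  l <- cm_to_morgan(l_cm)
  out <- numeric(length(l))
  for (L in as.numeric(chrom_map)) {
    okl <- l <= L
    if (any(okl)) out[okl] <- out[okl] + constant_ne_density(l[okl], 0, ne_fp, L)
  }
  out / 100
}

#' Detection-error correction of a theoretical rate
#'
#' Maps a theoretical IBD density tabulated on a length lattice `z` to the
#' observed-scale density at lengths `y`:
#' `corrected(y) = FP(y) + sum_z lambda(z) Recall(z) R(y|z) step` with a
#' Gaussian kernel `R(y|z)` truncated to `|y - z| <= window` and NOT
#' renormalized. The lattice must cover `[y - window, y + window]` (clipped at
#' zero); insufficient coverage is an error rather than silent zero-padding.
#'
#' @param lambda theoretical density per pair per cM, tabulated at `z_cm`.
#' @param z_cm tabulation lattice in cM (equally spaced at the model's step).
#' @param model an [error_model()].
#' @param y_cm output lengths in cM (default: `z_cm`).
#' @return corrected density per pair per cM at `y_cm`.
#' @export
corrected_rate <- function(lambda, z_cm, model, y_cm = z_cm) {
  stopifnot(inherits(model, "ibd_error_model"), length(lambda) == length(z_cm))
  step <- model$step_cm
  if (length(z_cm) > 1 && max(abs(diff(z_cm) - step)) > 1e-8)
    stop_domain("z lattice must be equally spaced at the model step (", step, " cM)")
  win <- if (model$sigma_cm > 0) model$window_cm else 0
  need_lo <- max(step / 2, min(y_cm) - win)
  need_hi <- max(y_cm) + win
  if (min(z_cm) > need_lo + step / 2 + 1e-9 || max(z_cm) < need_hi - step / 2 - 1e-9)
    stop_domain("lambda lattice does not cover [y - window, y + window]; extend the grid")
  rec <- model$recall(z_cm)
  if (model$sigma_cm > 0) {
    K <- outer(y_cm, z_cm, function(yy, zz) {
      d <- yy - zz
      ifelse(abs(d) <= model$window_cm + 1e-9, dnorm(d, 0, model$sigma_cm), 0)
    })
    conv <- as.vector(K %*% (lambda * rec)) * step
  } else {
    idx <- vapply(y_cm, function(yy) {
      j <- which(abs(z_cm - yy) < step / 2)
      if (length(j) != 1L) stop_domain("sigma = 0 requires y on the z lattice")
      j
    }, integer(1))
    conv <- lambda[idx] * rec[idx]
  }
  model$fp(y_cm) + conv
}

#' Inject detection errors into ground-truth IBD segments
#'
#' Forward simulation of the detection process: (1) for each lattice midpoint
#' in `fp_range_cm`, add `Poisson(nhap * FP(mid) * step)` false-positive
#' segments of that midpoint length; (2) keep each true segment with
#' probability `recall(length)`; (3) perturb kept lengths by Gaussian noise
#' with sd `sigma_cm`; (4) discard any segment shorter than `cutoff_cm`.
#'
#' @param segments data.frame with columns `id1`, `id2`, `chrom`, `length_cm`.
#' @param model an [error_model()].
#' @param nhap number of haplotype pairs the FP rate multiplies.
#' @param chrom_map a [chromosome_map()]; injected FPs are assigned to
#'   chromosomes with probability proportional to genetic length.
#' @param ids individual id pool for FP pair labels (default: ids present in
#'   `segments`).
#' @param cutoff_cm detection length cutoff in cM (default 8).
#' @param fp_range_cm range over which false positives are injected
#'   (default `c(8, 20)`).
#' @param seed RNG seed.
#' @return data.frame of corrupted segments (same columns); attributes
#'   `n_fp`, `n_dropped_recall`, `n_dropped_cutoff` record the bookkeeping.
#' @export
inject_errors <- function(segments, model, nhap, chrom_map, ids = NULL,
                          cutoff_cm = 8, fp_range_cm = c(8, 20), seed = NULL) {
  stopifnot(inherits(model, "ibd_error_model"))
  if (nrow(segments) > 0 && any(segments$length_cm <= 0))
    stop_domain("segment lengths must be > 0")
  with_seed(seed, {
    # (2) recall thinning, (3) length noise, (4) cutoff
    keep <- runif(nrow(segments)) < model$recall(segments$length_cm)
    out <- segments[keep, , drop = FALSE]
    if (model$sigma_cm > 0 && nrow(out) > 0)
      out$length_cm <- out$length_cm + rnorm(nrow(out), 0, model$sigma_cm)
    surv <- out$length_cm >= cutoff_cm
    n_cut <- sum(!surv)
    out <- out[surv, , drop = FALSE]
    # (1) false positives at lattice midpoints
    step <- model$step_cm
    mids <- seq(fp_range_cm[1] + step / 2, fp_range_cm[2] - step / 2, by = step)
    nfp_bin <- rpois(length(mids), nhap * model$fp(mids) * step)
    n_fp <- sum(nfp_bin)
    if (n_fp > 0) {
      ids <- ids %||% unique(c(as.character(segments$id1), as.character(segments$id2)))
      if (length(ids) < 2) stop_domain("need >= 2 individual ids to label false positives")
      pick <- t(vapply(seq_len(n_fp), function(k) sample(ids, 2L), character(2)))
      fp_df <- data.frame(
        id1 = pick[, 1], id2 = pick[, 2],
        chrom = sample(names(chrom_map), n_fp, replace = TRUE,
                       prob = as.numeric(chrom_map)),
        length_cm = rep(mids, nfp_bin), stringsAsFactors = FALSE)
      out <- rbind(out[, c("id1", "id2", "chrom", "length_cm")],
                   fp_df)
    }
    rownames(out) <- NULL
    attr(out, "n_fp") <- n_fp
    attr(out, "n_dropped_recall") <- sum(!keep)
    attr(out, "n_dropped_cutoff") <- n_cut
    out
  })
}
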