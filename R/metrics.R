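#' Image quality metrics: RMSE, PSNR, global SSIM
#'
#' `rmse()` is the root mean squared difference over the evaluation mask
#' (HU). `psnr()` is `10 log10(Pk^2/MSE)` dB with `Pk` the maximum
#' intensity over *both* images within the mask (so it is symmetric under
#' swap); identical images return `Inf`. `ssim()` is the single-window
#' (global) structural similarity computed from whole-mask means,
#' population variances and covariance,
#' `(2 a_r a_m + k1)(2 c + k2) / ((a_r^2 + a_m^2 + k1)(v_r + v_m + k2))`,
#' with `k1 = 0.01`, `k2 = 0.02`. Because the constants are not scaled by
#' the dynamic range, `rescale = TRUE` (used by [compare_methods()])
#' affinely maps both images to the unit interval over the mask (joint min/max)
#' before evaluating the formula; the default applies the formula to the
#' raw values.
#'
#' @param ref,mar reference and test [image2d()] (or bare matrices) on the
#'   same grid.
#' @param mask logical matrix of pixels to evaluate (default: all).
#' @return A scalar.
#' @name metrics
NULL

metric_values <- function(ref, mar, mask, what) {
  rv <- if (inherits(ref, "image2d")) ref$values else as.matrix(ref)
  mv <- if (inherits(mar, "image2d")) mar$values else as.matrix(mar)
  if (!identical(dim(rv), dim(mv)))
    stop(what, ": images are on different grids")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(rv), ncol(rv))
  if (!identical(dim(mask), dim(rv)))
    stop(what, ": mask does not match the image grid")
  list(ref = rv[mask], mar = mv[mask])
}

#' @rdname metrics
#' @export
rmse <- function(ref, mar, mask = NULL) {
  v <- metric_values(ref, mar, mask, "rmse")
  sqrt(mean((v$mar - v$ref)^2))
}

#' @rdname metrics
#' @export
psnr <- function(ref, mar, mask = NULL) {
  v <- metric_values(ref, mar, mask, "psnr")
  mse <- mean((v$mar - v$ref)^2)
  if (mse == 0) return(Inf)
  pk <- max(v$ref, v$mar)
  10 * log10(pk^2 / mse)
}

#' @rdname metrics
#' @param k1,k2 SSIM stabilization constants.
#' @param rescale affinely map both images to the unit interval over the mask before
#'   applying the formula.
#' @export
ssim <- function(ref, mar, mask = NULL, k1 = 0.01, k2 = 0.02,
                 rescale = FALSE) {
  v <- metric_values(ref, mar, mask, "ssim")
  r <- v$ref; m <- v$mar
  if (rescale) {
    lo <- min(r, m); hi <- max(r, m)
    if (hi > lo) { r <- (r - lo) / (hi - lo); m <- (m - lo) / (hi - lo) }
    else { r <- r * 0; m <- m * 0 }
  }
  n <- length(r)
  ar <- mean(r); am <- mean(m)
  vr <- mean((r - ar)^2); vm <- mean((m - am)^2) # population variance
  cv <- mean((r - ar) * (m - am))
  ((2 * ar * am + k1) * (2 * cv + k2)) /
    ((ar^2 + am^2 + k1) * (vr + vm + k2))
}

#' Evaluate MAR methods across a case set
#'
#' Runs each named corrector on every case's affected image, computes
#' RMSE/SSIM/PSNR against the case reference over the evaluation mask
#' (all pixels except the metal footprint by default, since metal pixels
#' are reinserted rather than corrected; SSIM uses the unit-interval affine
#' rescaling), aggregates per-method mean and SD, and tests each method
#' pair with a two-sided paired t-test per metric. A method failing on a
#' case is recorded and that case is dropped from its rows and pairwise
#' tests. Deterministic given deterministic correctors.
#'
#' @param cases list of `simulation_case` objects.
#' @param methods named list of functions `function(case) -> image2d`;
#'   the affected image itself is always evaluated under the name
#'   `"affected"`.
#' @param mask_policy `"exclude_metal"` (default) or `"all"`.
#' @return A `metrics_report`: `per_case` data.frame, `aggregate`
#'   data.frame (mean/sd per method and metric), `pairwise_p` data.frame,
#'   `failures`, and the recorded `mask_policy`.
#' @export
compare_methods <- function(cases, methods = list(),
                            mask_policy = c("exclude_metal", "all")) {
  mask_policy <- match.arg(mask_policy)
  methods <- c(list(affected = function(cs) cs$metal_affected), methods)
  rows <- list(); failures <- list()
  for (cs in cases) {
    mask <- if (mask_policy == "exclude_metal") !cs$metal_mask else NULL
    for (m in names(methods)) {
      out <- tryCatch(methods[[m]](cs), error = function(e) e)
      if (inherits(out, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(case_id = cs$case_id, method = m,
                     message = conditionMessage(out))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cs$case_id, method = m,
        rmse = rmse(cs$metal_inserted_ref, out, mask),
        ssim = ssim(cs$metal_inserted_ref, out, mask, rescale = TRUE),
        psnr = psnr(cs$metal_inserted_ref, out, mask))
    }
  }
  per_case <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_case, per_case$method), function(s)
    data.frame(method = s$method[1], n = nrow(s),
               rmse_mean = mean(s$rmse), rmse_sd = sd(s$rmse),
               ssim_mean = mean(s$ssim), ssim_sd = sd(s$ssim),
               psnr_mean = mean(s$psnr), psnr_sd = sd(s$psnr))))
  rownames(agg) <- NULL
  pw <- list()
  meth <- names(methods)
  for (a in seq_along(meth)) for (b in seq_along(meth)) {
    if (b <= a) next
    sa <- per_case[per_case$method == meth[a], ]
    sb <- per_case[per_case$method == meth[b], ]
    common <- intersect(sa$case_id, sb$case_id)
    if (length(common) < 2) next
    sa <- sa[match(common, sa$case_id), ]; sb <- sb[match(common, sb$case_id), ]
    for (metric in c("rmse", "ssim", "psnr")) {
      d <- sa[[metric]] - sb[[metric]]
      p <- if (all(d == 0) || sd(d) == 0) 1.0 else
        t.test(sa[[metric]], sb[[metric]], paired = TRUE)$p.value
      pw[[length(pw) + 1L]] <- data.frame(
        method_a = meth[a], method_b = meth[b], metric = metric,
        p_value = p, degenerate = all(d == 0) || sd(d) == 0)
    }
  }
  structure(list(per_case = per_case, aggregate = agg,
                 pairwise_p = if (length(pw)) do.call(rbind, pw) else NULL,
                 failures = if (length(failures)) do.call(rbind, failures) else NULL,
                 mask_policy = paste0(mask_policy,
                                      "; ssim rescaled to [0,1] over mask")),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$aggregate, digits = 4)
  invisible(x)
}
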