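#' Build a paired 2x2 contingency table of safety outcomes
#'
#' Counts paired binary outcomes (0 = unsafe, 1 = safe) for the two
#' approaches within the same hemispheres: `a` both safe, `b` frontal safe
#' only, `c` occipital safe only, `d` both unsafe.
#'
#' @param frontal,occipital equal-length vectors of 0/1 outcomes, one entry
#'   per paired hemisphere.
#' @return object of class `contingency_table` with fields `a`, `b`, `c`,
#'   `d`, `n`.
#' @export
build_contingency <- function(frontal, occipital) {
  if (length(frontal) != length(occipital))
    stop("paired vectors must have equal length")
  if (!all(c(frontal, occipital) %in% c(0, 1)))
    stop("outcomes must be binary 0/1 (0 = unsafe, 1 = safe)")
  structure(list(a = sum(frontal == 1 & occipital == 1),
                 b = sum(frontal == 1 & occipital == 0),
                 c = sum(frontal == 0 & occipital == 1),
                 d = sum(frontal == 0 & occipital == 0),
                 n = length(frontal)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("frontal safe", "frontal unsafe"),
                              c("occipital safe", "occipital unsafe")))
  print(m)
  cat("n =", x$n, "\n")
  invisible(x)
}

#' Safety proportions and discordant-pair splits
#'
#' @param t a [build_contingency()] table with `n > 0`.
#' @return list: `p_frontal_safe = (a+b)/n`, `p_occipital_safe = (a+c)/n`,
#'   `n_discordant = b+c`, and the discordant split fractions
#'   `frac_discordant_frontal = b/(b+c)`,
#'   `frac_discordant_occipital = c/(b+c)` (`NA` with a `defined = FALSE`
#'   flag when there are no discordant pairs).
#' @export
safety_proportions <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$n == 0) stop("empty contingency table")
  nd <- t$b + t$c
  list(p_frontal_safe = (t$a + t$b) / t$n,
       p_occipital_safe = (t$a + t$c) / t$n,
       n_discordant = nd,
       frac_discordant_frontal = if (nd > 0) t$b / nd else NA_real_,
       frac_discordant_occipital = if (nd > 0) t$c / nd else NA_real_,
       discordant_defined = nd > 0)
}

#' Mid-p McNemar test for paired binary outcomes
#'
#' Exact conditional test on the discordant pairs: with `n_d = b + c`
#' discordant pairs, `m = max(b, c)` and `X ~ Binomial(n_d, 1/2)` under the
#' null of no difference, the two-sided mid-p value is
#' `2 P(X >= m) - P(X = m)`, capped at 1, and defined as 1 when there are
#' no discordant pairs. The mid-p variant half-weights the point
#' probability, reducing the conservatism of the exact test.
#'
#' @param t a `contingency_table`, or the count `b` when `c` is given.
#' @param c_count discordant count `c` (when `t` is given as the count `b`).
#' @return p-value in `(0, 1]`.
#' @export
midp_mcnemar <- function(t, c_count = NULL) {
  if (inherits(t, "contingency_table")) {
    b <- t$b; cc <- t$c
  } else {
    b <- t; cc <- c_count
    if (is.null(cc)) stop("supply a contingency_table or both b and c")
  }
  nd <- b + cc
  if (nd == 0) return(1)
  m <- max(b, cc)
  p <- 2 * stats::pbinom(m - 1, nd, 0.5, lower.tail = FALSE) -
    stats::dbinom(m, nd, 0.5)
  min(p, 1)
}

#' Paired t-test with 95 percent confidence interval
#'
#' Standard one-sample t on the within-pair differences (`x - y`),
#' two-sided. Zero-variance differences are flagged (`degenerate = TRUE`)
#' instead of producing NaN: the mean difference and a zero-width CI are
#' returned with `t_stat`/`p` of 0/1 when the mean difference is also 0,
#' `NA` otherwise.
#'
#' @param x,y paired real-valued vectors (e.g. coverage fractions for the
#'   frontal and occipital approach, per hemisphere).
#' @return list: `mean_diff`, `ci95_lo`, `ci95_hi`, `t_stat`, `p`, `df`,
#'   `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(list(mean_diff = md, ci95_lo = md, ci95_hi = md,
                t_stat = if (md == 0) 0 else NA_real_,
                p = if (md == 0) 1 else NA_real_,
                df = length(d) - 1, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE, conf.level = 0.95)
  list(mean_diff = unname(tt$estimate), ci95_lo = tt$conf.int[1],
       ci95_hi = tt$conf.int[2], t_stat = unname(tt$statistic),
       p = tt$p.value, df = unname(tt$parameter), degenerate = FALSE)
}

#' Mean with t-based 95 percent confidence interval
#'
#' @param values numeric vector, length >= 2.
#' @return list: `mean`, `ci95_lo`, `ci95_hi`.
#' @export
summarize_mean_ci <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  q <- stats::qt(0.975, n - 1)
  list(mean = m, ci95_lo = m - q * se, ci95_hi = m + q * se)
}

#' Render a connection-count heat map
#'
#' Writes the count matrix as CSV (bit-exact) and as a PNG with a fixed
#' 0..`scale_max` color scale, rows labeled by region and columns by the
#' four putamen segments.
#'
#' @param counts non-negative integer matrix (regions x segments) with
#'   dimnames.
#' @param scale_max top of the fixed color scale (e.g. 2 x n_subjects).
#' @param png_path,csv_path output paths (`NULL` to skip either).
#' @return the matrix, invisibly.
#' @export
render_heatmap <- function(counts, scale_max, png_path = NULL,
                           csv_path = NULL) {
  if (any(counts < 0)) stop("negative entries in count matrix")
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(counts), csv_path, row.names = TRUE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
    nr <- nrow(counts); nc <- ncol(counts)
    graphics::par(mar = c(8, 8, 2, 4))
    graphics::image(seq_len(nc), seq_len(nr), t(counts[rev(seq_len(nr)), ,
                                                       drop = FALSE]),
                    zlim = c(0, scale_max), col = pal, axes = FALSE,
                    xlab = "", ylab = "")
    graphics::axis(1, at = seq_len(nc), labels = colnames(counts), las = 2)
    graphics::axis(2, at = seq_len(nr), labels = rev(rownames(counts)),
                   las = 1)
    graphics::box()
  }
  invisible(counts)
}

#' Read a heat-map CSV back as an integer matrix
#'
#' @param csv_path path written by [render_heatmap()].
#' @return integer matrix with dimnames.
#' @export
read_heatmap_csv <- function(csv_path) {
  df <- utils::read.csv(csv_path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
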