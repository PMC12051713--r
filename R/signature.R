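#' Correlate every gene with the per-sample dispersal score
#'
#' Computes, for each gene, the Pearson correlation between its expression
#' across samples and the samples' dispersal scores, with a two-sided
#' p-value from the t distribution on n - 2 degrees of freedom.
#' Constant-expression genes have undefined correlation and are excluded;
#' their count is reported via `message()` and the attribute
#' `"n_constant_excluded"`.
#'
#' @param expr An [expression_matrix()] with `sample_scores` set and at
#'   least 3 samples.
#' @return A `data.frame` (class `gene_correlation_table`) with columns
#'   `gene`, `r`, `p`, `n`.
#' @export
correlate_genes_with_dispersal <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(expr$sample_scores))
    stop("expression matrix carries no per-sample dispersal scores",
         call. = FALSE)
  n <- ncol(expr$values)
  if (n < 3)
    stop("correlation screen requires at least 3 samples", call. = FALSE)
  s <- expr$sample_scores
  if (sd(s) == 0)
    stop("dispersal scores are constant; correlations undefined",
         call. = FALSE)
  v <- expr$values
  gene_sd <- apply(v, 1, sd)
  const <- gene_sd == 0 | is.na(gene_sd)
  if (any(const))
    message("excluding ", sum(const),
            " constant-expression gene(s) from the screen")
  v <- v[!const, , drop = FALSE]

  # vectorized Pearson r across all genes at once
  vc <- v - rowMeans(v)
  sc <- as.numeric(s - mean(s))
  r <- as.numeric(vc %*% sc) / (sqrt(rowSums(vc^2)) * sqrt(sum(sc^2)))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  out <- data.frame(gene = rownames(v), r = r, p = p, n = n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_correlation_table", "data.frame")
  attr(out, "n_constant_excluded") <- sum(const)
  out
}

#' Select positively and significantly correlated genes
#'
#' Keeps genes with `r > 0` and `p < alpha`. No multiple-testing
#' correction is applied by default (a single two-sided threshold with the
#' positivity constraint); set `adjust = "BH"` for a
#' Benjamini-Hochberg-adjusted screen.
#'
#' @param table A `gene_correlation_table` from
#'   [correlate_genes_with_dispersal()].
#' @param alpha Significance threshold in (0, 1); default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Character vector of selected gene names, lexicographically
#'   sorted.
#' @export
select_positive_significant <- function(table, alpha = 0.05,
                                        adjust = c("none", "BH")) {
  stopifnot(inherits(table, "gene_correlation_table"),
            alpha > 0, alpha < 1)
  adjust <- match.arg(adjust)
  p <- if (adjust == "BH") stats::p.adjust(table$p, "BH") else table$p
  sort(table$gene[table$r > 0 & p < alpha])
}

#' Intersect two gene signatures
#'
#' Exact set intersection, returned in deterministic lexicographic order.
#' Used to keep only genes whose expression correlates with dispersal in
#' both contexts (e.g. in vitro and in vivo screens).
#'
#' @param set_a,set_b Character vectors of gene names.
#' @return Sorted character vector.
#' @export
intersect_signatures <- function(set_a, set_b) {
  sort(intersect(as.character(set_a), as.character(set_b)))
}

#' Per-sample signature Z-score
#'
#' Each signature gene is standardized across samples to mean 0 and
#' standard deviation 1 (population sd, i.e. the n-denominator form;
#' configurable), and the per-sample score is the mean of the standardized
#' values over the signature genes. Genes absent from the matrix are
#' skipped with a warning; constant genes cannot be standardized and are
#' likewise skipped.
#'
#' @param expr An [expression_matrix()] with at least 2 samples.
#' @param genes Character vector of signature gene names.
#' @param sd_type `"population"` (divide by sd with n denominator;
#'   default) or `"sample"` (n - 1 denominator). Both give identical
#'   sample rankings; only the scale differs.
#' @return Named numeric vector of per-sample scores (mean 0 across
#'   samples by construction).
#' @export
signature_zscore <- function(expr, genes,
                             sd_type = c("population", "sample")) {
  stopifnot(inherits(expr, "expression_matrix"))
  sd_type <- match.arg(sd_type)
  n <- ncol(expr$values)
  if (n < 2) stop("Z-scoring requires at least 2 samples", call. = FALSE)
  genes <- as.character(genes)
  missing_g <- setdiff(genes, rownames(expr$values))
  if (length(missing_g) == length(genes))
    stop("none of the signature genes is present in the matrix",
         call. = FALSE)
  if (length(missing_g))
    warning("signature gene(s) absent from the matrix, skipped: ",
            paste(missing_g, collapse = ", "), call. = FALSE)
  v <- expr$values[setdiff(genes, missing_g), , drop = FALSE]
  sds <- apply(v, 1, sd)
  if (sd_type == "population") sds <- sds * sqrt((n - 1) / n)
  const <- sds == 0
  if (any(const)) {
    warning("constant signature gene(s) skipped: ",
            paste(rownames(v)[const], collapse = ", "), call. = FALSE)
    v <- v[!const, , drop = FALSE]
    sds <- sds[!const]
    if (!nrow(v))
      stop("no non-constant signature gene present", call. = FALSE)
  }
  z <- (v - rowMeans(v)) / sds
  colMeans(z)
}

#' Stratify samples by signature score
#'
#' @param scores Named numeric per-sample scores.
#' @param rule `"median"` (score above the median is `"high"`, ties at
#'   the median go to `"low"`), `"tertile_extremes"` (bottom tertile
#'   `"low"`, top tertile `"high"`, middle `NA`), or `"threshold:v"` for a
#'   fixed numeric cut `v` (strictly above goes `"high"`).
#' @return Character vector of `"low"`/`"high"` labels (possibly `NA`
#'   under the tertile rule), named like `scores`.
#' @export
stratify_by_score <- function(scores, rule = "median") {
  stopifnot(is.numeric(scores), length(rule) == 1, is.character(rule))
  if (rule == "median") {
    m <- median(scores)
    out <- ifelse(scores > m, "high", "low")
    if (all(out == "low"))
      warning("degenerate split: no score above the median", call. = FALSE)
  } else if (rule == "tertile_extremes") {
    qs <- quantile(scores, c(1 / 3, 2 / 3))
    out <- rep(NA_character_, length(scores))
    out[scores <= qs[1]] <- "low"
    out[scores > qs[2]] <- "high"
  } else if (grepl("^threshold:", rule)) {
    v <- suppressWarnings(as.numeric(sub("^threshold:", "", rule)))
    if (is.na(v))
      stop("threshold rule needs a numeric cut, e.g. \"threshold:0\"",
           call. = FALSE)
    out <- ifelse(scores > v, "high", "low")
  } else {
    stop("unknown stratification rule '", rule,
         "': use \"median\", \"tertile_extremes\" or \"threshold:v\"",
         call. = FALSE)
  }
  stats::setNames(out, names(scores))
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Fits the product-limit estimator per group and compares the groups
#' with the log-rank test, whose statistic is referred to a chi-square
#' distribution with k - 1 degrees of freedom. (Survival-curve
#' comparisons reported as "chi-squared tests" correspond to this test.)
#'
#' @param surv A [survival_table()] with at least 2 groups and at least
#'   one observed event.
#' @return List with `fit` (the `survival::survfit` object), `curves`
#'   (data frame of per-group step curves: `group`, `time`, `n_risk`,
#'   `n_event`, `survival`), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(surv) {
  stopifnot(inherits(surv, "survival_table"))
  if (length(unique(surv$group)) < 2)
    stop("survival comparison requires at least 2 groups", call. = FALSE)
  if (sum(surv$event) == 0)
    stop("no observed events: log-rank test undefined", call. = FALSE)
  df_ <- as.data.frame(surv)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df_)
  sdf <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = df_)
  k <- length(sdf$n)
  sf <- summary(fit)
  curves <- data.frame(
    group = sub("^group=", "", as.character(sf$strata)),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    survival = sf$surv, stringsAsFactors = FALSE)
  list(fit = fit, curves = curves, chisq = unname(sdf$chisq),
       df = k - 1L, p = unname(pchisq(sdf$chisq, k - 1L,
                                      lower.tail = FALSE)))
}

#' Read an expression matrix from delimited text
#'
#' Expects genes as rows: first column gene names, header row of sample
#' names. A row named `dispersal_score` (configurable) is stripped from
#' the gene matrix and stored as the per-sample scores.
#'
#' @param path Input path.
#' @param delimiter Field delimiter; inferred from the extension by
#'   default.
#' @param score_row Name of the optional row holding per-sample dispersal
#'   scores.
#' @param sample_scores Optional numeric vector overriding/providing the
#'   scores directly.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, delimiter = NULL,
                                   score_row = "dispersal_score",
                                   sample_scores = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = delimiter, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (is.null(sample_scores) && score_row %in% genes) {
    sample_scores <- m[score_row, ]
    m <- m[setdiff(genes, score_row), , drop = FALSE]
  }
  expression_matrix(m, sample_scores)
}

#' Write an expression matrix to delimited text
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @param score_row Row name under which `sample_scores` (if present) are
#'   written.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, delimiter = "\t",
                                    score_row = "dispersal_score") {
  stopifnot(inherits(expr, "expression_matrix"))
  m <- expr$values
  if (!is.null(expr$sample_scores))
    m <- rbind(m, matrix(expr$sample_scores, 1,
                         dimnames = list(score_row, colnames(m))))
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a survival table from delimited text
#'
#' Expects columns `time`, `event`, `group` (header required).
#'
#' @param path Input path.
#' @param delimiter Field delimiter; inferred from the extension by
#'   default.
#' @return A [survival_table()].
#' @export
read_survival_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = delimiter, stringsAsFactors = FALSE)
  for (cn in c("time", "event", "group"))
    if (!cn %in% names(df))
      stop("survival table is missing column '", cn, "'", call. = FALSE)
  survival_table(df$time, df$event, df$group)
}
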