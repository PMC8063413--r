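#' Define a genetic cross
#'
#' Parents are given as per-locus unordered allele pairs (a single locus
#' may be given as a plain length-2 character vector). Lethal genotypes
#' (e.g. a balancer homozygote such as CyO/CyO) are removed before
#' renormalizing expected progeny fractions; a class map can collapse
#' genotypes into named phenotypic classes. Allele order within a locus is
#' irrelevant everywhere: genotypes are normalized to sorted `a/b` strings
#' (multi-locus genotypes joined with `"; "`).
#'
#' @param parent1,parent2 List of character vectors of length 2, one per
#'   locus (or a single length-2 vector for one locus).
#' @param lethal Character vector of inviable genotype patterns, e.g.
#'   `"CyO/CyO"`. A pattern may name a single locus; a progeny genotype is
#'   inviable when any of its loci matches any pattern.
#' @param classes Optional named character vector mapping normalized
#'   genotype strings to class names; unmapped genotypes keep their
#'   genotype string as class.
#' @return Object of class `cross_scheme`.
#' @examples
#' cross_scheme(c("KI", "CyO"), c("KI", "CyO"), lethal = "CyO/CyO")
#' @export
cross_scheme <- function(parent1, parent2, lethal = character(),
                         classes = NULL) {
  norm_parent <- function(p, which) {
    if (is.character(p)) p <- list(p)
    if (!is.list(p) || !all(vapply(p, length, integer(1)) == 2L)) {
      stop(which, " must be a list of length-2 allele vectors")
    }
    lapply(p, as.character)
  }
  parent1 <- norm_parent(parent1, "parent1")
  parent2 <- norm_parent(parent2, "parent2")
  if (length(parent1) != length(parent2)) {
    stop("parents must have the same number of loci")
  }
  lethal <- vapply(lethal, normalize_genotype, character(1), USE.NAMES = FALSE)
  if (!is.null(classes)) {
    names(classes) <- vapply(names(classes), normalize_genotype, character(1),
                             USE.NAMES = FALSE)
  }
  structure(list(parent1 = parent1, parent2 = parent2, lethal = lethal,
                 classes = classes),
            class = "cross_scheme")
}

# "b/a" -> "a/b"; multi-locus "x/y; a/b" normalized per locus.
normalize_genotype <- function(g) {
  loci <- strsplit(g, ";", fixed = TRUE)[[1]]
  paste(vapply(trimws(loci), function(l) {
    paste(sort(trimws(strsplit(l, "/", fixed = TRUE)[[1]])), collapse = "/")
  }, character(1)), collapse = "; ")
}

#' @export
print.cross_scheme <- function(x, ...) {
  fmt <- function(p) paste(vapply(p, paste, character(1), collapse = "/"),
                           collapse = "; ")
  cat("<cross_scheme> ", fmt(x$parent1), " x ", fmt(x$parent2), "\n", sep = "")
  if (length(x$lethal)) cat("  lethal:", paste(x$lethal, collapse = ", "), "\n")
  invisible(x)
}

#' Expected progeny class fractions
#'
#' Enumerates parental gametes under equal segregation and independent
#' assortment, forms all progeny genotypes with their probabilities, drops
#' lethal genotypes, renormalizes, and aggregates by the scheme's class
#' map.
#'
#' @param scheme A [cross_scheme].
#' @return Named numeric vector of class fractions summing to 1, with
#'   attribute `genotype_fractions` (pre-class-map, post-lethality).
#' @examples
#' # balancer intercross: homozygous balancer progeny die
#' expected_fractions(
#'   cross_scheme(c("KI", "CyO"), c("KI", "CyO"), lethal = "CyO/CyO"))
#' @export
expected_fractions <- function(scheme) {
  stopifnot(inherits(scheme, "cross_scheme"))
  n_loci <- length(scheme$parent1)
  gametes <- function(parent) {
    combos <- expand.grid(lapply(parent, identity), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    combos
  }
  g1 <- gametes(scheme$parent1)
  g2 <- gametes(scheme$parent2)
  probs <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(g1))) {
    for (j in seq_len(nrow(g2))) {
      geno <- paste(vapply(seq_len(n_loci), function(l) {
        paste(sort(c(g1[i, l], g2[j, l])), collapse = "/")
      }, character(1)), collapse = "; ")
      p <- 1 / (nrow(g1) * nrow(g2))
      probs[[geno]] <- (if (is.null(probs[[geno]])) 0 else probs[[geno]]) + p
    }
  }
  geno_p <- unlist(as.list(probs))
  viable <- !vapply(names(geno_p), genotype_is_lethal, logical(1),
                    lethal = scheme$lethal)
  if (!any(viable)) stop("all progeny genotypes are lethal")
  geno_p <- geno_p[viable]
  geno_p <- geno_p / sum(geno_p)
  cls <- names(geno_p)
  if (!is.null(scheme$classes)) {
    mapped <- scheme$classes[cls]
    cls <- ifelse(is.na(mapped), cls, mapped)
  }
  out <- tapply(geno_p, cls, sum)
  out <- stats::setNames(as.numeric(out), names(out))
  attr(out, "genotype_fractions") <- geno_p
  out
}

genotype_is_lethal <- function(geno, lethal) {
  if (!length(lethal)) return(FALSE)
  loci <- trimws(strsplit(geno, ";", fixed = TRUE)[[1]])
  geno %in% lethal || any(loci %in% lethal)
}

#' Goodness-of-fit of observed progeny counts to expected fractions
#'
#' Two classes: exact two-sided binomial test. More classes: chi-square
#' goodness of fit, replaced by an exact multinomial test (tail summation
#' over all outcomes no more probable than the observed one) when expected
#' counts are small and full enumeration is tractable.
#'
#' @param observed Named integer vector of class counts.
#' @param expected Named fractions summing to 1 (e.g. from
#'   [expected_fractions()]); names must cover `observed`.
#' @return List of class `deviation_test`: `method`, `statistic` (chi-square
#'   branch only), `p_value`, `observed`, `expected_counts`.
#' @export
deviation_test <- function(observed, expected) {
  if (is.null(names(observed)) || is.null(names(expected))) {
    stop("observed and expected must be named")
  }
  expected <- expected[names(observed)]
  if (any(is.na(expected))) stop("expected fractions missing for some classes")
  if (abs(sum(expected) - 1) > 1e-8) stop("expected fractions must sum to 1")
  n <- sum(observed)
  if (n <= 0) stop("total count must be positive")
  if (any(expected == 0 & observed > 0)) {
    stop("nonzero observed count in a class with expected fraction 0")
  }
  k <- length(observed)
  exp_counts <- n * expected
  if (k == 2L) {
    p <- stats::binom.test(observed[1], n, p = expected[1])$p.value
    method <- "exact binomial"
    statistic <- NA_real_
  } else if (any(exp_counts < 5) && multinom_enum_size(n, k) <= 2e5) {
    p <- exact_multinomial_p(as.integer(observed), as.numeric(expected))
    method <- "exact multinomial"
    statistic <- NA_real_
  } else {
    if (any(exp_counts < 5)) {
      warning("expected counts < 5 and enumeration intractable; ",
              "chi-square approximation used")
    }
    ct <- suppressWarnings(stats::chisq.test(observed, p = expected))
    p <- ct$p.value
    method <- "chi-square goodness of fit"
    statistic <- unname(ct$statistic)
  }
  structure(list(method = method, statistic = statistic,
                 p_value = unname(p), observed = observed,
                 expected_counts = exp_counts),
            class = "deviation_test")
}

#' @export
print.deviation_test <- function(x, ...) {
  cat("Progeny deviation test (", x$method, ")\n", sep = "")
  tab <- rbind(observed = x$observed, expected = round(x$expected_counts, 2))
  print(tab)
  if (!is.na(x$statistic)) cat(sprintf("chi-squared = %.3f, ", x$statistic))
  cat(sprintf("p = %.4g\n", x$p_value))
  invisible(x)
}

multinom_enum_size <- function(n, k) choose(n + k - 1, k - 1)

# Exact multinomial p-value: sum of probabilities of all outcomes whose
# probability does not exceed the observed outcome's (with tolerance for
# ties in floating point).
exact_multinomial_p <- function(observed, prob) {
  n <- sum(observed)
  k <- length(observed)
  obs_lp <- stats::dmultinom(observed, prob = prob, log = TRUE)
  total <- 0
  counts <- integer(k)
  recurse <- function(idx, remaining) {
    if (idx == k) {
      counts[k] <<- remaining
      lp <- stats::dmultinom(counts, prob = prob, log = TRUE)
      if (lp <= obs_lp + 1e-10) total <<- total + exp(lp)
      return(invisible(NULL))
    }
    for (c_i in 0:remaining) {
      counts[idx] <<- c_i
      recurse(idx + 1L, remaining - c_i)
    }
  }
  recurse(1L, n)
  min(total, 1)
}

#' Decision battery for group comparisons of continuous measurements
#'
#' Mirrors the common phenotype-analysis workflow: per-group
#' D'Agostino-Pearson normality testing first; when every group is
#' Gaussian and Bartlett's test accepts equal variances, the parametric
#' branch runs (one-way ANOVA, or a pooled t-test for two groups, with
#' Bonferroni-corrected pairwise t-tests); otherwise the nonparametric
#' branch runs (Kruskal-Wallis, or Mann-Whitney for two groups, with
#' Bonferroni-corrected pairwise Mann-Whitney tests). Groups smaller than
#' 8 cannot be normality-tested and force the nonparametric branch (noted
#' in the output).
#'
#' @param data Data frame with columns `group` and `value`.
#' @param alpha Level used for the normality and variance gate decisions
#'   (default 0.05).
#' @return Object of class `stats_battery`: `branch` (`"parametric"` or
#'   `"nonparametric"`), `normality_p` per group, `bartlett_p`,
#'   `global_test`, `global_stat`, `global_p`, `pairwise` (matrix of
#'   Bonferroni-adjusted p-values, `NULL` for two groups), `notes`.
#' @export
stats_battery <- function(data, alpha = 0.05) {
  stopifnot(is.data.frame(data), all(c("group", "value") %in% names(data)))
  data$group <- factor(data$group)
  groups <- levels(data$group)
  if (length(groups) < 2L) stop("need at least 2 groups")
  ns <- table(data$group)
  if (any(ns < 3L)) {
    stop("group '", names(ns)[which(ns < 3L)[1]], "' has fewer than 3 values")
  }
  notes <- character()

  can_test_norm <- all(ns >= 8L)
  normality_p <- stats::setNames(rep(NA_real_, length(groups)), groups)
  if (can_test_norm) {
    for (g in groups) {
      normality_p[g] <- dagostino_pearson(data$value[data$group == g])$p_value
    }
    gaussian <- all(normality_p > alpha)
  } else {
    notes <- c(notes, "group(s) with n < 8: normality untestable, nonparametric branch forced")
    gaussian <- FALSE
  }
  bartlett_p <- NA_real_
  if (gaussian) {
    bartlett_p <- stats::bartlett.test(value ~ group, data = data)$p.value
    parametric <- bartlett_p > alpha
    if (!parametric) notes <- c(notes, "unequal variances (Bartlett): nonparametric branch")
  } else {
    parametric <- FALSE
  }

  two <- length(groups) == 2L
  pairwise <- NULL
  if (parametric) {
    if (two) {
      tt <- stats::t.test(value ~ group, data = data, var.equal = TRUE)
      global_test <- "t-test (pooled)"
      global_stat <- unname(tt$statistic); global_p <- tt$p.value
    } else {
      fit <- stats::aov(value ~ group, data = data)
      an <- summary(fit)[[1]]
      global_test <- "one-way ANOVA"
      global_stat <- an[["F value"]][1]; global_p <- an[["Pr(>F)"]][1]
      pairwise <- stats::pairwise.t.test(data$value, data$group,
                                         p.adjust.method = "bonferroni")$p.value
    }
    branch <- "parametric"
  } else {
    if (two) {
      wt <- suppressWarnings(stats::wilcox.test(value ~ group, data = data))
      global_test <- "Mann-Whitney"
      global_stat <- unname(wt$statistic); global_p <- wt$p.value
    } else {
      kw <- stats::kruskal.test(value ~ group, data = data)
      global_test <- "Kruskal-Wallis"
      global_stat <- unname(kw$statistic); global_p <- kw$p.value
      pairwise <- suppressWarnings(
        stats::pairwise.wilcox.test(data$value, data$group,
                                    p.adjust.method = "bonferroni")$p.value)
    }
    branch <- "nonparametric"
  }
  structure(list(branch = branch, normality_p = normality_p,
                 bartlett_p = bartlett_p, global_test = global_test,
                 global_stat = global_stat, global_p = global_p,
                 pairwise = pairwise, notes = notes, alpha = alpha),
            class = "stats_battery")
}

#' @export
print.stats_battery <- function(x, ...) {
  cat("Measurement statistics battery —", x$branch, "branch\n")
  if (!all(is.na(x$normality_p))) {
    cat("  normality p (D'Agostino-Pearson):",
        paste(sprintf("%s=%.3g", names(x$normality_p), x$normality_p),
              collapse = ", "), "\n")
  }
  if (!is.na(x$bartlett_p)) cat(sprintf("  Bartlett p = %.3g\n", x$bartlett_p))
  cat(sprintf("  %s: statistic = %.3f, p = %.4g\n", x$global_test,
              x$global_stat, x$global_p))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Bonferroni-adjusted):\n")
    print(round(x$pairwise, 4))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness test and the Anscombe-Glynn kurtosis
#' test into the K-squared omnibus statistic (chi-square, 2 df). Requires
#' n >= 8. Constant samples are reported as maximally non-Gaussian
#' (p = 0).
#'
#' @param x Numeric vector, length >= 8.
#' @return List with `statistic` (K-squared), `p_value`, `z_skewness`,
#'   `z_kurtosis`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  if (stats::sd(x) == 0) {
    return(list(statistic = Inf, p_value = 0, z_skewness = Inf,
                z_kurtosis = Inf))
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # skewness (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  d <- 1 / sqrt(log(sqrt(w2)))
  a <- sqrt(2 / (w2 - 1))
  z1 <- d * log(y / a + sqrt((y / a)^2 + 1))

  # kurtosis (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eb2) / sqrt(vb2)
  sb2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sb2 * (2 / sb2 + sqrt(1 + 4 / sb2^2))
  inner <- (1 - 2 / aa) / (1 + xx * sqrt(2 / (aa - 4)))
  z2 <- ((1 - 2 / (9 * aa)) - sign(inner) * abs(inner)^(1/3)) /
    sqrt(2 / (9 * aa))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2)
}

#' Per-group mean, s.e.m. and n
#'
#' @param data Data frame with columns `group` and `value`.
#' @return Data frame with `group`, `n`, `mean`, `sd`, `sem` (NA when
#'   n = 1).
#' @export
summarize_groups <- function(data) {
  stopifnot(is.data.frame(data), all(c("group", "value") %in% names(data)))
  if (!nrow(data)) stop("empty data")
  groups <- unique(as.character(data$group))
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- data$value[data$group == g]
    if (!length(v)) stop("empty group '", g, "'")
    s <- if (length(v) > 1L) stats::sd(v) else NA_real_
    data.frame(group = g, n = length(v), mean = mean(v), sd = s,
               sem = s / sqrt(length(v)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
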