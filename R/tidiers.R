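# broom-style tidiers for the package's fitted/result objects.

#' Tidy and glance methods
#'
#' broom-style summaries: `tidy()` returns one row per estimated component,
#' `glance()` a one-row model summary.
#'
#' @param x A margindiff result object.
#' @param ... Unused.
#' @return A tibble.
#' @name margindiff-tidiers
NULL

#' @rdname margindiff-tidiers
#' @export
tidy.variance_components <- function(x, ...) {
  tibble(
    component = c("sigma2_G", "sigma2_E"),
    estimate = c(x$sigma2_G, x$sigma2_E)
  )
}

#' @rdname margindiff-tidiers
#' @export
glance.variance_components <- function(x, ...) {
  tibble(
    H2 = x$H2, sigma2_G = x$sigma2_G, sigma2_E = x$sigma2_E,
    truncated = x$truncated, n_genotypes = x$n_genotypes, n_plants = x$n_plants
  )
}

#' @rdname margindiff-tidiers
#' @export
tidy.qst_result <- function(x, ...) {
  tibble(
    trait = x$trait %||% NA_character_,
    term = c("sigma2_B", "sigma2_W", "qst"),
    estimate = c(x$sigma2_B, x$sigma2_W, x$qst)
  )
}

#' @rdname margindiff-tidiers
#' @export
glance.qst_result <- function(x, ...) {
  tibble(
    trait = x$trait %||% NA_character_, qst = x$qst, sigma2_B = x$sigma2_B,
    sigma2_W = x$sigma2_W, mode = x$mode, truncated = x$truncated,
    n_groups = x$n_groups, n_genotypes = x$n_genotypes
  )
}

#' @rdname margindiff-tidiers
#' @export
glance.qst_fst_test <- function(x, ...) {
  tibble(
    trait = x$trait %||% NA_character_, qst = x$qst, quantile = x$quantile,
    p = x$p, n_boot = x$n_boot, mode = x$mode
  )
}

#' @rdname margindiff-tidiers
#' @export
tidy.qst_fst_test <- function(x, ...) {
  tibble(
    draw = seq_len(x$n_boot), qst = x$qst_draws, fst = x$fst_draws
  )
}

#' @rdname margindiff-tidiers
#' @export
tidy.top_snp_set <- function(x, ...) {
  tibble(
    trait = x$trait %||% NA_character_,
    snp_id = c(x$positive, x$negative),
    tail = rep(c("positive", "negative"), c(length(x$positive), length(x$negative)))
  )
}

#' @rdname margindiff-tidiers
#' @export
glance.fst_result <- function(x, ...) {
  ov <- attr(x, "fst_overall")
  tibble(pair = names(ov) %||% unique(x$pair), fst_overall = unname(ov))
}

#' @rdname margindiff-tidiers
#' @export
tidy.top_overlap <- function(x, ...) {
  tibble(
    tail_a = rep(rownames(x$counts), 2),
    tail_b = rep(colnames(x$counts), each = 2),
    n = as.vector(x$counts)
  )
}

#' @rdname margindiff-tidiers
#' @export
glance.top_overlap <- function(x, ...) {
  tibble(total = x$total, expected = x$expected, p = x$p)
}
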