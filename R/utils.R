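#' @importFrom rlang abort %||% .data .env :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   bind_rows bind_cols left_join inner_join anti_join distinct across n
#'   row_number first last desc if_else
#' @importFrom stats median sd rnorm runif rpois rbinom prcomp lm coef aov
#'   pbinom pt rchisq qt setNames approx cor var quantile
#' @importFrom utils head tail
NULL

# run `expr` under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name),
          class = "evotrace_invalid_argument")
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  ok_high <- if (strict_upper) x < upper else x <= upper
  if (!ok_low || !ok_high) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x),
          class = "evotrace_invalid_argument")
  }
  invisible(x)
}

assert_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s.", name,
                  paste(missing, collapse = ", ")),
          class = "evotrace_invalid_argument")
  }
  invisible(df)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(length, gc_fraction) {
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
             gc_fraction / 2, (1 - gc_fraction) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = probs), collapse = "")
}
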