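#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reward breakdown into a long component tibble
#'
#' @param x A `reward_breakdown` from [total_reward()].
#' @param ... Unused.
#' @return A tibble with columns `component`, `value` (NA for vacuous
#'   accuracy components).
#' @export
tidy.reward_breakdown <- function(x, ...) {
  comps <- c("s_entity", "s_triplet", "s_rare", "s_tag", "s_length",
             "r_acc", "r_fmt", "r_total")
  tibble::tibble(
    component = comps,
    value = vapply(comps, function(k) as.numeric(x[[k]]), numeric(1))
  )
}

#' @rdname tidy.reward_breakdown
#' @export
glance.reward_breakdown <- function(x, ...) {
  tibble::tibble(
    doc_id = x$doc_id, r_total = x$r_total, r_acc = x$r_acc,
    r_fmt = x$r_fmt, parse_ok = x$parse_ok
  )
}

#' Tidy and summarize strict-match metrics
#'
#' @param x A `ke_metrics` tibble from [evaluate_extraction()].
#' @param ... Unused.
#' @return `tidy()` returns the per-type rows; `glance()` the overall
#'   (`ALL`) row together with the level and averaging mode.
#' @export
tidy.ke_metrics <- function(x, ...) {
  out <- x[x$type != "ALL", ]
  class(out) <- setdiff(class(out), "ke_metrics")
  out
}

#' @rdname tidy.ke_metrics
#' @export
glance.ke_metrics <- function(x, ...) {
  out <- x[x$type == "ALL", c("tp", "fp", "fn", "precision", "recall", "f1")]
  out$level <- attr(x, "level")
  out$average <- attr(x, "average")
  class(out) <- setdiff(class(out), "ke_metrics")
  out
}
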