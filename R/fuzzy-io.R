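#' Serialize fuzzy numbers to and from JSON
#'
#' Parabolic and crisp families serialize compactly as
#' `{"family", "center", "spread"}`; generic families carry their explicit
#' endpoint arrays `{"family": "alphacut", "alphas", "left", "right"}`.
#'
#' @param x A `"fuzzy_number"`.
#' @param grid Grid used to rebuild parabolic/crisp families on parse.
#' @param txt JSON text or a parsed list.
#' @return `fuzzy_to_json()` returns a JSON string; `fuzzy_from_json()`
#'   returns a `"fuzzy_number"`.
#' @export
fuzzy_to_json <- function(x) {
  fam <- attr(x, "family")
  obj <- if (identical(fam, "parabolic")) {
    list(family = "parabolic", center = attr(x, "center"),
         spread = attr(x, "spread"))
  } else if (identical(fam, "crisp")) {
    list(family = "crisp", center = attr(x, "center"))
  } else {
    list(family = "alphacut", alphas = x$alpha, left = x$left,
         right = x$right)
  }
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' @rdname fuzzy_to_json
#' @export
fuzzy_from_json <- function(txt, grid = alpha_grid()) {
  obj <- if (is.character(txt)) jsonlite::fromJSON(txt) else txt
  switch(obj$family,
    parabolic = parabolic_fuzzy_number(obj$center, obj$spread, grid),
    crisp = crisp_fuzzy_number(obj$center, grid),
    alphacut = fuzzy_number(obj$alphas, obj$left, obj$right),
    stop("unknown fuzzy-number family: ", obj$family))
}
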