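#' Restriction enzyme definition
#'
#' A restriction enzyme is described by its recognition sequence and the
#' cut offset within it: the cut is placed `cut_offset` bases after the
#' start of a recognition match, so HindIII (A^AGCTT) has offset 1 and
#' MboI (^GATC) offset 0. Fragments inherit genomic coordinates from the
#' cut positions; overhang fill-in is not modelled.
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (A/C/G/T only, length >= 4).
#' @param cut_offset Bases from recognition start to the cut
#'   (0 <= cut_offset <= nchar(recognition)).
#' @return An object of class `enzyme`.
#' @examples
#' hindiii()
#' mboi()
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!grepl("^[ACGT]+$", recognition) || nchar(recognition) < 4) {
    cb_stop("recognition must be ACGT-only and at least 4 nt")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    cb_stop("cut_offset must lie within the recognition sequence")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "enzyme")
}

#' @rdname restriction_enzyme
#' @export
hindiii <- function() restriction_enzyme("HindIII", "AAGCTT", 1L)

#' @rdname restriction_enzyme
#' @export
mboi <- function() restriction_enzyme("MboI", "GATC", 0L)

#' Look up a bundled enzyme by name
#' @param name "HindIII" or "MboI".
#' @return An `enzyme` object.
#' @export
get_enzyme <- function(name) {
  switch(toupper(name),
         HINDIII = hindiii(),
         MBOI = mboi(),
         cb_stop("unknown enzyme: ", name,
                 class = "chicbench_config_error"))
}

#' @export
print.enzyme <- function(x, ...) {
  cut <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                substr(x$recognition, x$cut_offset + 1,
                       nchar(x$recognition)))
  cat("<enzyme>", x$name, cut, "\n")
  invisible(x)
}
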