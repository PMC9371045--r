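#' Cautery state labels
#'
#' The five cautery states and their integer codes. An electrosurgical
#' generator is either off, activated in cut or coagulate mode with the blade
#' in air, or activated in either mode with the blade touching tissue (the
#' *energy event*). Codes are fixed so that cut-in-air is class 1 and
#' cut-on-tissue is class 3; confusion matrices throughout the package use
#' this class order.
#'
#' @return `stateLevels()` returns a named integer vector mapping state names
#'   to codes 0--4.
#' @examples
#' stateLevels()
#' stateName(3)
#' stateCode("coag_air")
#' isTissueState(c("off", "cut_tissue"))
#' @export
stateLevels <- function() {
  c(off = 0L, cut_air = 1L, coag_air = 2L, cut_tissue = 3L, coag_tissue = 4L)
}

#' @rdname stateLevels
#' @param code integer state code(s) in 0--4.
#' @export
stateName <- function(code) {
  lv <- stateLevels()
  idx <- match(as.integer(code), lv)
  if (anyNA(idx)) {
    stop("unknown state code(s): ",
         paste(unique(code[is.na(idx)]), collapse = ", "))
  }
  names(lv)[idx]
}

#' @rdname stateLevels
#' @param name state name(s); one of `"off"`, `"cut_air"`, `"coag_air"`,
#'   `"cut_tissue"`, `"coag_tissue"`.
#' @export
stateCode <- function(name) {
  lv <- stateLevels()
  code <- lv[match(as.character(name), names(lv))]
  if (anyNA(code)) {
    stop("unknown state name(s): ",
         paste(unique(name[is.na(code)]), collapse = ", "))
  }
  unname(code)
}

# Accept either codes or names, return integer codes.
asStateCode <- function(x) {
  if (is.numeric(x)) {
    bad <- !(as.integer(x) %in% stateLevels())
    if (any(bad)) stop("unknown state code(s): ", paste(unique(x[bad]), collapse = ", "))
    as.integer(x)
  } else {
    stateCode(x)
  }
}

#' @rdname stateLevels
#' @param x state codes or names.
#' @export
isTissueState <- function(x) {
  asStateCode(x) %in% stateCode(c("cut_tissue", "coag_tissue"))
}

#' @rdname stateLevels
#' @export
isAirState <- function(x) {
  asStateCode(x) %in% stateCode(c("cut_air", "coag_air"))
}

#' @rdname stateLevels
#' @export
stateMode <- function(x) {
  code <- asStateCode(x)
  out <- rep(NA_character_, length(code))
  out[code %in% stateCode(c("cut_air", "cut_tissue"))] <- "cut"
  out[code %in% stateCode(c("coag_air", "coag_tissue"))] <- "coag"
  out
}
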