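#' Standardise a personal name into canonical comparable form
#'
#' Case-folds, strips diacritics, removes punctuation (hyphens and apostrophes
#' are deleted rather than replaced by spaces, so "Anna-Marie" and "Annamarie"
#' canonicalise identically) and collapses whitespace. Input may be a bare
#' surname or a "Surname, Forename" pair; the comma splits the two parts.
#' Empty or whitespace-only input is flagged missing rather than raising an
#' error, because upstream records legitimately lack names.
#'
#' @param raw_name character vector of raw names.
#' @return a data.frame with columns `surname`, `forename` (NA when absent)
#'   and `missing` (logical).
#' @examples
#' standardise_name("  O'Brien , Anna-Marie ")
#' @export
standardise_name <- function(raw_name) {
  raw_name <- as.character(raw_name)
  parts <- strsplit(ifelse(is.na(raw_name), "", raw_name), ",", fixed = TRUE)
  sur <- canonical_string(vapply(parts, function(p) if (length(p) >= 1) p[[1]] else "", ""))
  fore <- canonical_string(vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", ""))
  missing <- is.na(sur)
  data.frame(surname = sur, forename = fore, missing = missing,
             stringsAsFactors = FALSE)
}

#' @rdname standardise_name
#' @param x character vector.
#' @export
canonical_string <- function(x) {
  x <- toupper(as.character(x))
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  x <- gsub("[^A-Z]", "", x)
  x[is.na(x) | x == ""] <- NA_character_
  x
}

#' Generate a synthetic postcode-to-authority lookup
#'
#' The real national postcode directory is licensed, so linkage strength
#' levels that depend on local-authority geography (exact postcode, same
#' authority, neighbouring authority) are evaluated against a generated
#' universe: `n_authorities` area codes arranged on a ring with random chord
#' edges defining a symmetric neighbour relation, each holding roughly
#' `n_postcodes / n_authorities` postcodes in standard outward+inward form.
#'
#' @param n_postcodes total postcodes to generate.
#' @param n_authorities number of local authorities.
#' @param extra_edges random extra neighbour edges beyond the ring.
#' @param seed integer seed.
#' @return an object of class `postcode_lookup`: list with `table`
#'   (postcode, outward, authority) and `neighbours` (named list of character
#'   vectors, symmetric).
#' @export
make_postcode_lookup <- function(n_postcodes = 1000, n_authorities = 50,
                                 extra_edges = 25, seed = 1) {
  stopifnot(n_authorities >= 2, n_postcodes >= n_authorities)
  set.seed(seed)
  auth <- sprintf("A%02d", seq_len(n_authorities))
  # outward codes are tied to the authority so that outward-code blocking
  # approximates authority blocking, as in real geography
  area_letters <- paste0(LETTERS[((seq_len(n_authorities) - 1) %% 26) + 1],
                         LETTERS[((seq_len(n_authorities) - 1) %/% 26) + 1])
  per <- ceiling(n_postcodes / n_authorities)
  auth_of <- rep(seq_len(n_authorities), each = per)[seq_len(n_postcodes)]
  outward <- paste0(area_letters[auth_of], sample(1:9, n_postcodes, TRUE))
  inward <- paste0(sample(1:9, n_postcodes, TRUE),
                   sample(LETTERS, n_postcodes, TRUE),
                   sample(LETTERS, n_postcodes, TRUE))
  pc <- paste(outward, inward)
  dup <- duplicated(pc)
  while (any(dup)) {
    inward[dup] <- paste0(sample(1:9, sum(dup), TRUE),
                          sample(LETTERS, sum(dup), TRUE),
                          sample(LETTERS, sum(dup), TRUE))
    pc <- paste(outward, inward)
    dup <- duplicated(pc)
  }
  edges <- cbind(seq_len(n_authorities),
                 c(seq_len(n_authorities)[-1], 1L))
  if (extra_edges > 0) {
    more <- cbind(sample(n_authorities, extra_edges, TRUE),
                  sample(n_authorities, extra_edges, TRUE))
    more <- more[more[, 1] != more[, 2], , drop = FALSE]
    edges <- rbind(edges, more)
  }
  nb <- lapply(seq_len(n_authorities), function(i) {
    j <- c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])
    sort(unique(auth[j]))
  })
  names(nb) <- auth
  structure(list(table = data.frame(postcode = pc, outward = outward,
                                    authority = auth[auth_of],
                                    stringsAsFactors = FALSE),
                 neighbours = nb),
            class = "postcode_lookup")
}

#' @export
print.postcode_lookup <- function(x, ...) {
  cat("<postcode_lookup> ", nrow(x$table), " postcodes, ",
      length(x$neighbours), " authorities\n", sep = "")
  invisible(x)
}

#' Canonicalise raw postcodes against a lookup
#'
#' Uppercases, strips all internal whitespace and reinserts the single space
#' before the 3-character inward part. Codes absent from the lookup are
#' passed through flagged invalid with no authority, never rejected.
#'
#' @param raw character vector of raw postcodes.
#' @param lookup a [make_postcode_lookup()] object.
#' @return data.frame with `postcode`, `outward`, `valid`, `authority`.
#' @export
canonicalise_postcode <- function(raw, lookup) {
  x <- toupper(gsub("[[:space:][:punct:]]", "", as.character(raw)))
  x[x == ""] <- NA_character_
  long_enough <- !is.na(x) & nchar(x) >= 5
  canon <- ifelse(long_enough,
                  paste(substr(x, 1, nchar(x) - 3),
                        substring(x, nchar(x) - 2)),
                  x)
  i <- match(canon, lookup$table$postcode)
  data.frame(postcode = canon,
             outward = ifelse(long_enough, substr(x, 1, nchar(x) - 3), NA),
             valid = !is.na(i),
             authority = lookup$table$authority[i],
             stringsAsFactors = FALSE)
}

#' Build the canonical identifier chronology for each participant
#'
#' Takes the raw contact table (one row per recorded contact, with the name,
#' date of birth and postcode captured at that contact), canonicalises every
#' field, sorts by contact date and merges consecutive duplicates, so the
#' history retains every distinct identifier state in time order. Participants
#' whose contacts carry no identifiers at all are flagged rather than dropped.
#'
#' @param contacts data.frame with columns `participant_id`, `contact_date`,
#'   `forename`, `surname`, `dob`, `postcode`.
#' @param lookup postcode lookup used for canonicalisation.
#' @return data.frame, class `identifier_chronology`: one row per retained
#'   identifier state with canonical fields, `authority`, `postcode_valid`
#'   and `empty_history` flag.
#' @export
build_identifier_chronology <- function(contacts, lookup) {
  stopifnot(nrow(contacts) >= 1)
  o <- order(contacts$participant_id, as.Date(contacts$contact_date))
  x <- contacts[o, , drop = FALSE]
  pc <- canonicalise_postcode(x$postcode, lookup)
  h <- data.frame(participant_id = x$participant_id,
                  contact_date = as.Date(x$contact_date),
                  surname = canonical_string(x$surname),
                  forename = canonical_string(x$forename),
                  dob = as.Date(x$dob),
                  postcode = pc$postcode,
                  outward = pc$outward,
                  postcode_valid = pc$valid,
                  authority = pc$authority,
                  stringsAsFactors = FALSE)
  key <- paste(h$surname, h$forename, h$dob, h$postcode, sep = "\r")
  same_as_prev <- c(FALSE, key[-1] == key[-nrow(h)] &
                      h$participant_id[-1] == h$participant_id[-nrow(h)])
  h <- h[!same_as_prev, , drop = FALSE]
  no_id <- is.na(h$surname) & is.na(h$forename) & is.na(h$dob) &
    is.na(h$postcode)
  empty <- tapply(no_id, h$participant_id, all)
  h$empty_history <- as.logical(empty[as.character(h$participant_id)])
  rownames(h) <- NULL
  class(h) <- c("identifier_chronology", "data.frame")
  h
}
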