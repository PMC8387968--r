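# Taxonomy harmonization and identification-class assignment.
#
# Verified and suggested names pass through the same harmonization: strip
# infraspecific epithets and hybrid markers, then resolve synonyms against a
# pluggable backbone (a two-column synonym map plus a three-column
# accepted-name/genus/family map). The class of an attempt is then a pure
# function of the two harmonized names.

#' Build a taxonomy map
#'
#' A taxonomy map couples an accepted-name backbone (accepted binomial, genus,
#' family) with an optional synonym table. Accepted names map to themselves,
#' so harmonization is idempotent.
#'
#' @param accepted data.frame with columns `accepted_name`, `genus`, `family`.
#'   `genus` may be omitted; it is then derived as the first token of the
#'   accepted binomial.
#' @param synonyms optional data.frame with columns `synonym`, `accepted_name`.
#' @return An object of class `taxonomy_map`.
#' @export
taxonomy_map <- function(accepted, synonyms = NULL) {
  if (!is.data.frame(accepted) || !all(c("accepted_name", "family") %in%
                                       names(accepted)))
    stop("'accepted' needs columns accepted_name and family", call. = FALSE)
  accepted_name <- trimws(as.character(accepted$accepted_name))
  if (anyDuplicated(tolower(accepted_name)))
    stop("duplicate accepted names in taxonomy", call. = FALSE)
  genus <- if ("genus" %in% names(accepted)) as.character(accepted$genus)
           else vapply(strsplit(accepted_name, "\\s+"), `[`, "", 1)
  acc <- data.frame(accepted_name = accepted_name, genus = genus,
                    family = as.character(accepted$family),
                    stringsAsFactors = FALSE)
  syn_lookup <- character(0)
  if (!is.null(synonyms) && nrow(synonyms)) {
    if (!all(c("synonym", "accepted_name") %in% names(synonyms)))
      stop("'synonyms' needs columns synonym and accepted_name", call. = FALSE)
    syn_lookup <- setNames(trimws(as.character(synonyms$accepted_name)),
                           tolower(.strip_name(as.character(synonyms$synonym))))
  }
  obj <- structure(list(
    accepted = acc,
    accepted_lookup = setNames(acc$accepted_name, tolower(acc$accepted_name)),
    family_lookup = setNames(acc$family, tolower(acc$accepted_name)),
    synonym_lookup = syn_lookup
  ), class = "taxonomy_map")
  # idempotence guard: a synonym target must itself resolve to an accepted name
  bad <- setdiff(tolower(unname(syn_lookup)), tolower(acc$accepted_name))
  if (length(bad))
    stop("synonym targets not in accepted backbone: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  obj
}

#' @export
print.taxonomy_map <- function(x, ...) {
  cat(sprintf("taxonomy_map: %d accepted names, %d families, %d synonyms\n",
              nrow(x$accepted), length(unique(x$accepted$family)),
              length(x$synonym_lookup)))
  invisible(x)
}

# Strip hybrid markers and infraspecific epithets: keep the first two tokens
# ("Genus epithet"); rank markers ("subsp.", "var.") and everything after the
# epithet are dropped.
.strip_name <- function(name) {
  name <- gsub("×", " ", name, fixed = TRUE)   # hybrid sign
  name <- gsub("\\s+", " ", trimws(name))
  toks <- strsplit(name, " ", fixed = TRUE)
  vapply(toks, function(tk) paste(head(tk, 2L), collapse = " "), "")
}

#' Harmonize a taxon name
#'
#' Strips infraspecific epithets (tokens after the binomial, including rank
#' markers such as "subsp." and "var.") and hybrid markers, then resolves
#' synonyms to their accepted name. Unknown names are returned stripped but
#' otherwise unchanged.
#'
#' @param raw_name character vector of names; empty strings are an error.
#' @param taxonomy a [taxonomy_map()].
#' @param log_unknown if `TRUE`, unknown names are reported once via
#'   [message()].
#' @return Character vector of harmonized names.
#' @examples
#' tax <- taxonomy_map(
#'   data.frame(accepted_name = "Dactylorhiza majalis", family = "Orchidaceae"),
#'   data.frame(synonym = "Dactylorhiza baltica",
#'              accepted_name = "Dactylorhiza majalis"))
#' harmonize_name("Dactylorhiza baltica", tax)
#' @export
harmonize_name <- function(raw_name, taxonomy, log_unknown = FALSE) {
  stopifnot(inherits(taxonomy, "taxonomy_map"))
  raw_name <- as.character(raw_name)
  if (any(is.na(raw_name) | trimws(raw_name) == ""))
    stop("empty taxon name cannot be harmonized", call. = FALSE)
  stripped <- .strip_name(raw_name)
  key <- tolower(stripped)
  out <- stripped
  hit_syn <- key %in% names(taxonomy$synonym_lookup)
  out[hit_syn] <- unname(taxonomy$synonym_lookup[key[hit_syn]])
  key2 <- tolower(out)
  hit_acc <- key2 %in% names(taxonomy$accepted_lookup)
  out[hit_acc] <- unname(taxonomy$accepted_lookup[key2[hit_acc]])
  if (log_unknown && any(!hit_acc))
    message("names not in taxonomy backbone: ",
            paste(unique(out[!hit_acc]), collapse = ", "))
  out
}

.genus_of <- function(name) vapply(strsplit(name, " ", fixed = TRUE),
                                   `[`, "", 1)

.family_of <- function(name, taxonomy) {
  fam <- unname(taxonomy$family_lookup[tolower(name)])
  fam
}

#' Assign the identification class of one or more attempts
#'
#' The first suggestion is scored against the verified name after both are
#' harmonized: `species` on an exact (case-insensitive) match, else `genus`
#' when the genera agree, else `family` when both names resolve to the same
#' family in the taxonomy backbone, else `none`. An empty suggestion is
#' `none`.
#'
#' @param verified_name,suggested_name character vectors (recycled to common
#'   length); the suggestion may be `""` or `NA` for "no suggestion".
#' @param taxonomy a [taxonomy_map()]; every verified name must resolve to an
#'   accepted name in it.
#' @param use_alternatives score `;`-separated alternative suggestions and
#'   keep the best class (off by default: only the first suggestion counts).
#' @return Character vector with values among [identification_classes()].
#' @export
classify_observation <- function(verified_name, suggested_name, taxonomy,
                                 use_alternatives = FALSE) {
  n <- max(length(verified_name), length(suggested_name))
  verified_name <- rep_len(as.character(verified_name), n)
  suggested_name <- rep_len(as.character(suggested_name), n)

  ver <- harmonize_name(verified_name, taxonomy)
  unknown <- !(tolower(ver) %in% names(taxonomy$accepted_lookup))
  if (any(unknown))
    stop("verified names not in taxonomy: ",
         paste(unique(ver[unknown]), collapse = ", "), call. = FALSE)

  if (use_alternatives) {
    cls_rank <- setNames(seq_along(identification_classes()),
                         identification_classes())
    return(vapply(seq_len(n), function(i) {
      alts <- strsplit(suggested_name[i], ";", fixed = TRUE)[[1]]
      alts <- trimws(alts)
      alts <- alts[!is.na(alts) & alts != ""]
      if (!length(alts)) return("none")
      cls <- classify_observation(rep(verified_name[i], length(alts)), alts,
                                  taxonomy, use_alternatives = FALSE)
      identification_classes()[min(cls_rank[cls])]
    }, ""))
  }

  out <- rep("none", n)
  has_sugg <- !is.na(suggested_name) & trimws(suggested_name) != ""
  if (any(has_sugg)) {
    sug <- harmonize_name(suggested_name[has_sugg], taxonomy)
    v <- ver[has_sugg]
    cls <- rep("none", length(sug))
    same_sp <- tolower(sug) == tolower(v)
    same_gen <- !same_sp & tolower(.genus_of(sug)) == tolower(.genus_of(v))
    fam_s <- .family_of(sug, taxonomy)
    fam_v <- .family_of(v, taxonomy)
    same_fam <- !same_sp & !same_gen & !is.na(fam_s) & !is.na(fam_v) &
      tolower(fam_s) == tolower(fam_v)
    cls[same_fam] <- "family"
    cls[same_gen] <- "genus"
    cls[same_sp] <- "species"
    out[has_sugg] <- cls
  }
  out
}

#' Classify every observation in a table
#'
#' @param observations observation table (see [load_observations()]).
#' @param taxonomy a [taxonomy_map()].
#' @param use_alternatives see [classify_observation()].
#' @return The observation table with a `class` column added and
#'   `verified_name` replaced by its harmonized form.
#' @export
classify_observations <- function(observations, taxonomy,
                                  use_alternatives = FALSE) {
  observations <- validate_observations(observations)
  observations$verified_name <-
    harmonize_name(observations$verified_name, taxonomy)
  observations$class <- classify_observation(
    observations$verified_name, observations$suggested_name, taxonomy,
    use_alternatives = use_alternatives)
  observations
}
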