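## A candidate instance is one sentence paired with one specific mention
## pair: the unit of classification. Labels are POS / NEG / REMOVED, and the
## `provenance` field records every labeling / filtering step that touched
## the instance (DS, CP, TW, HP, TOPK). After distant-supervision labeling,
## the only permitted transitions are POS -> REMOVED and NEG -> REMOVED.

new_instance <- function(sent, e1, e2, label = NA_character_,
                         provenance = character(), gold = NA) {
  structure(
    list(sentence = sent, e1 = e1, e2 = e2, label = label,
         provenance = provenance, gold = gold),
    class = "ds_instance"
  )
}

#' @export
print.ds_instance <- function(x, ...) {
  cat(sprintf("<instance %s/%s %s[%d,%d)-%s[%d,%d) label=%s prov=%s>\n",
              x$sentence$doc_id, x$sentence$sent_id,
              x$e1$kb_id, x$e1$start, x$e1$end,
              x$e2$kb_id, x$e2$start, x$e2$end,
              x$label, paste(x$provenance, collapse = "+")))
  invisible(x)
}

as_instances <- function(lst) structure(lst, class = "ds_instances")

#' @export
`[.ds_instances` <- function(x, i) as_instances(unclass(x)[i])

#' @export
print.ds_instances <- function(x, ...) {
  s <- instance_stats(x)
  cat(sprintf("<%d instances: %d POS, %d NEG, %d REMOVED>\n",
              length(x), s$pos, s$neg, s$removed))
  invisible(x)
}

#' Count instances by label
#'
#' @param instances A `ds_instances` collection.
#' @return List with integer fields `pos`, `neg`, `removed`.
#' @export
instance_stats <- function(instances) {
  labels <- vapply(instances, `[[`, "", "label")
  list(pos = sum(labels == "POS"), neg = sum(labels == "NEG"),
       removed = sum(labels == "REMOVED"))
}

instance_labels <- function(instances) {
  vapply(instances, `[[`, "", "label")
}

## Instances that participate in training/evaluation (REMOVED never does).
active_instances <- function(instances) {
  instances[instance_labels(instances) != "REMOVED"]
}

mention_row <- function(mentions, i) {
  list(mention_id = mentions$mention_id[i], entity_type = mentions$entity_type[i],
       start = mentions$start[i], end = mentions$end[i], kb_id = mentions$kb_id[i])
}

## Token gap between the inner boundaries of the two mention spans.
instance_gap <- function(inst) {
  if (inst$e1$end <= inst$e2$start) inst$e2$start - inst$e1$end
  else inst$e1$start - inst$e2$end
}

#' Write instances as JSONL
#'
#' One record per instance: sentence coordinates, both mention spans and
#' kb_ids, the label, and the provenance trail.
#'
#' @param instances A `ds_instances` collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instances <- function(instances, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (inst in instances) {
    rec <- list(doc_id = inst$sentence$doc_id, sent_id = inst$sentence$sent_id,
                e1 = inst$e1, e2 = inst$e2, label = inst$label,
                provenance = I(inst$provenance))
    if (!is.na(inst$gold)) rec$gold <- inst$gold
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
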