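#' Construct a task atlas
#'
#' A task atlas lists the activation maps to be predicted, grouped into task
#' domains, and carries the per-map loss weights. Weights are chosen so that
#' every domain — rather than every map — contributes equally to the training
#' loss: a map in a domain with `n_d` maps gets weight `1 / (n_domains * n_d)`,
#' so the weights sum to one.
#'
#' @param maps data.frame with columns `map` (unique map name) and `domain`.
#' @return an object of class `task_atlas`: list with `maps` (data.frame with
#'   `map`, `domain`, `weight`), `domains` (character), `n_maps`.
#' @export
#' @examples
#' atlas <- task_atlas(data.frame(
#'   map = c("A1", "A2", "B1"), domain = c("A", "A", "B")))
#' sum(atlas$maps$weight)  # 1
task_atlas <- function(maps) {
  stopifnot(is.data.frame(maps), all(c("map", "domain") %in% names(maps)))
  if (anyDuplicated(maps$map)) stop("map names must be unique")
  maps$map <- as.character(maps$map)
  maps$domain <- as.character(maps$domain)
  domains <- unique(maps$domain)
  n_in <- table(maps$domain)
  maps$weight <- 1 / (length(domains) * as.numeric(n_in[maps$domain]))
  structure(list(maps = maps, domains = domains, n_maps = nrow(maps)),
            class = "task_atlas")
}

#' Default desk-scale task atlas
#'
#' Seven task domains (motor, language, working memory, relational, emotion,
#' social, incentive processing) with 14 activation maps in total — a
#' desk-scale stand-in for a full task battery, keeping the uneven
#' maps-per-domain structure that makes domain weighting non-trivial.
#'
#' @return a [task_atlas()].
#' @export
default_task_atlas <- function() {
  task_atlas(data.frame(
    map = c("MOTOR_LH", "MOTOR_RH", "MOTOR_T",
            "LANGUAGE_STORY", "LANGUAGE_MATH",
            "WM_2BK", "WM_FACE",
            "RELATIONAL_REL", "RELATIONAL_MATCH",
            "EMOTION_FACES", "EMOTION_SHAPES",
            "SOCIAL_TOM", "SOCIAL_RANDOM",
            "GAMBLING_REWARD"),
    domain = c("MOTOR", "MOTOR", "MOTOR",
               "LANGUAGE", "LANGUAGE",
               "WM", "WM",
               "RELATIONAL", "RELATIONAL",
               "EMOTION", "EMOTION",
               "SOCIAL", "SOCIAL",
               "GAMBLING")))
}

#' @export
print.task_atlas <- function(x, ...) {
  cat("task_atlas:", x$n_maps, "maps in", length(x$domains), "domains\n")
  print(x$maps, row.names = FALSE)
  invisible(x)
}
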