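#' Study design: subjects, groups and their recordings
#'
#' Binds subject/group assignments to per-condition [eeg_recording] objects.
#' Subjects missing either condition are kept but flagged incomplete; group
#' contrasts require two groups.
#'
#' @param subjects data.frame with columns `subject_id`, `group`.
#' @param recordings named list of [eeg_recording]s keyed `"<subject_id>.<condition>"`.
#' @param conditions character vector of condition labels expected per subject.
#' @return An object of class `study_design`.
#' @export
study_design <- function(subjects, recordings,
                         conditions = c("baseline", "task")) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "group") %in% names(subjects)))
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$group <- as.character(subjects$group)
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject ids")
  want <- as.vector(outer(subjects$subject_id, conditions, paste, sep = "."))
  complete <- vapply(subjects$subject_id, function(s)
    all(paste(s, conditions, sep = ".") %in% names(recordings)), logical(1))
  subjects$complete <- unname(complete)
  extra <- setdiff(names(recordings), want)
  if (length(extra)) stop("recordings not in design: ", paste(extra, collapse = ", "))
  structure(list(subjects = subjects, recordings = recordings,
                 conditions = conditions),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<study_design> %d subjects (%s); %d/%d complete; conditions: %s\n",
              nrow(x$subjects),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              sum(x$subjects$complete), nrow(x$subjects),
              paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Fetch one recording from a study
#' @param design a [study_design].
#' @param subject_id subject identifier.
#' @param condition condition label.
#' @return The [eeg_recording], or `NULL` if absent.
#' @export
get_recording <- function(design, subject_id, condition) {
  design$recordings[[paste(subject_id, condition, sep = ".")]]
}

#' Load a study from a YAML configuration
#'
#' The config lists the sampling rate, the group labels in use, and one entry
#' per subject giving its group and per-condition ASCII epoch file paths
#' (relative paths resolve against the config's directory):
#'
#' ```yaml
#' fs: 1024
#' groups: [typical, dyslexic]
#' conditions: [baseline, task]
#' subjects:
#'   - id: S01
#'     group: typical
#'     baseline: S01_baseline.txt
#'     task: S01_task.txt
#' ```
#'
#' A missing or unreadable file flags that subject incomplete rather than
#' aborting the whole study; an unknown group label or an empty subject list
#' is a configuration error.
#'
#' @param config path to the YAML study file.
#' @return A [study_design].
#' @export
load_study <- function(config) {
  cfg <- yaml::read_yaml(config)
  if (is.null(cfg$subjects) || length(cfg$subjects) == 0L)
    stop("study config has an empty subject list")
  groups <- cfg$groups %||% c("typical", "dyslexic")
  conditions <- cfg$conditions %||% c("baseline", "task")
  base_dir <- dirname(normalizePath(config))
  subs <- do.call(rbind, lapply(cfg$subjects, function(s) {
    if (is.null(s$id) || is.null(s$group))
      stop("each subject needs 'id' and 'group'")
    if (!s$group %in% groups)
      stop(sprintf("unknown group label '%s' for subject %s", s$group, s$id))
    data.frame(subject_id = as.character(s$id), group = s$group,
               stringsAsFactors = FALSE)
  }))
  recordings <- list()
  for (s in cfg$subjects) {
    for (cond in conditions) {
      p <- s[[cond]]
      if (is.null(p)) next
      if (!grepl("^/", p)) p <- file.path(base_dir, p)
      if (!file.exists(p)) {
        warning(sprintf("subject %s: missing %s file %s (flagged incomplete)",
                        s$id, cond, p), call. = FALSE)
        next
      }
      rec <- read_ascii_epochs(p, fs = cfg$fs)
      rec$subject_id <- as.character(s$id)
      rec$group <- s$group
      rec$condition <- cond
      recordings[[paste(s$id, cond, sep = ".")]] <- rec
    }
  }
  study_design(subs, recordings, conditions = conditions)
}

#' Write a study (ASCII epoch files + YAML config) to a directory
#'
#' @param design a [study_design] whose recordings are in memory.
#' @param dir output directory, created if needed.
#' @param digits significant digits for [write_ascii_epochs].
#' @return Path to the written YAML config, invisibly.
#' @export
write_study <- function(design, dir, digits = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- NULL
  subjects <- lapply(seq_len(nrow(design$subjects)), function(i) {
    sid <- design$subjects$subject_id[i]
    entry <- list(id = sid, group = design$subjects$group[i])
    for (cond in design$conditions) {
      rec <- get_recording(design, sid, cond)
      if (is.null(rec)) next
      fs <<- rec$fs
      fname <- sprintf("%s_%s.txt", sid, cond)
      write_ascii_epochs(rec, file.path(dir, fname), digits = digits)
      entry[[cond]] <- fname
    }
    entry
  })
  cfg <- list(fs = fs, groups = unique(design$subjects$group),
              conditions = design$conditions, subjects = subjects)
  path <- file.path(dir, "study.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
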