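## Object-level access control: users, access groups, permissions.
##
## Every securable object (investigation, study, protocol) is an environment
## carrying `owner` (a user id) and `grants` (a list of group/level pairs,
## keyed by group id). Objects are private by default: only the creator can
## read, write or delete until a group is granted "read_only" or "full"
## rights. Objects inside an investigation additionally honour the
## investigation's own grants (union semantics).

#' Create a user reference
#'
#' Users are trusted identities (no authentication layer): a unique id and a
#' display name. Most functions accept either an `xr_user` or a bare id
#' string.
#'
#' @param id Unique user identifier.
#' @param name Display name; defaults to the id.
#' @return An `xr_user` object.
#' @export
#' @examples
#' alice <- xr_user("alice", "Alice A")
xr_user <- function(id, name = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name), class = "xr_user")
}

user_id <- function(user) {
  if (inherits(user, "xr_user")) user$id else as.character(user)
}

#' Create an access group
#'
#' A named set of users that can be granted read-only or full rights on an
#' object. Each investigation automatically receives one at creation; further
#' groups can be created freely for sharing.
#'
#' @param id Group identifier.
#' @param members Users (or user ids) initially in the group.
#' @return An `xr_access_group` environment.
#' @export
access_group <- function(id, members = character()) {
  g <- new.env(parent = emptyenv())
  g$id <- id
  g$members <- unique(vapply(as.list(members), user_id, character(1)))
  class(g) <- "xr_access_group"
  g
}

#' Add or remove a group member
#'
#' Both operations are idempotent.
#'
#' @param group An `xr_access_group`.
#' @param user A user or user id.
#' @return The group, invisibly.
#' @export
add_member <- function(group, user) {
  stopifnot(inherits(group, "xr_access_group"))
  group$members <- union(group$members, user_id(user))
  invisible(group)
}

#' @rdname add_member
#' @export
remove_member <- function(group, user) {
  stopifnot(inherits(group, "xr_access_group"))
  group$members <- setdiff(group$members, user_id(user))
  invisible(group)
}

is_securable <- function(object) {
  is.environment(object) && !is.null(object$owner)
}

# Actions implied by each permission level.
level_covers <- function(level, action) {
  switch(level,
    full = action %in% c("read", "write", "delete"),
    read_only = action == "read",
    FALSE
  )
}

#' Check whether a user may act on an object
#'
#' Objects are automatically private: only their creator has any rights until
#' an access group is granted on them. A grant of `read_only` confers read;
#' `full` confers read, write and delete. Objects contained in an
#' investigation (studies) also honour grants made on the investigation, and
#' the investigation's creator has full rights on its contents.
#'
#' @param user A user or user id.
#' @param object A securable object (investigation, study or protocol).
#' @param action One of `"read"`, `"write"`, `"delete"`.
#' @return `TRUE` or `FALSE`.
#' @export
check_permission <- function(user, object, action = c("read", "write", "delete")) {
  action <- match.arg(action)
  if (is.null(object) || !is_securable(object)) {
    xr_abort("NoSuchObject", "object does not exist or is not securable")
  }
  uid <- user_id(user)
  holders <- list(object)
  if (!is.null(object$investigation)) holders <- c(holders, list(object$investigation))
  for (h in holders) {
    if (identical(h$owner, uid)) return(TRUE)
    for (g in h$grants) {
      if (uid %in% g$group$members && level_covers(g$level, action)) return(TRUE)
    }
  }
  FALSE
}

#' Grant or revoke group access on an object
#'
#' Only a user with full permission on the object (its creator, or a member
#' of a group granted `full`) may administer grants. Granting the same group
#' twice updates the single existing entry (idempotent); revoking restores
#' the prior permission matrix exactly.
#'
#' @param object A securable object.
#' @param group An `xr_access_group`.
#' @param level `"read_only"` or `"full"`.
#' @param caller The user performing the administration.
#' @return The object, invisibly.
#' @export
grant_access <- function(object, group, level = c("read_only", "full"), caller) {
  level <- match.arg(level)
  stopifnot(inherits(group, "xr_access_group"))
  if (!check_permission(caller, object, "write") ||
      !check_permission(caller, object, "delete")) {
    xr_abort("AccessDenied", "caller lacks full permission to administer grants")
  }
  object$grants[[group$id]] <- list(group = group, level = level)
  invisible(object)
}

#' @rdname grant_access
#' @export
revoke_access <- function(object, group, caller) {
  stopifnot(inherits(group, "xr_access_group"))
  if (!check_permission(caller, object, "write") ||
      !check_permission(caller, object, "delete")) {
    xr_abort("AccessDenied", "caller lacks full permission to administer grants")
  }
  object$grants[[group$id]] <- NULL
  invisible(object)
}
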