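; Toy scrambled-eggs domain.  12 action classes: the brownie set plus
; turn_off (the stove must be switched off at the end of the recipe).
(define (domain eggs)
  (:types thing location place amount substance device pool - object
          takeable source - thing
          container pourable - takeable
          openable - location)
  (:objects bowl frying_pan plate - container
            oil_bottle - pourable
            faucet open_egg_shell - source
            egg_shell empty_egg_shell - pool
            counter sink stove_top hands - location
            cupboard_tl cupboard_bl fridge egg_box - openable
            counter_place fridge_place stove_place - place
            1 2 - amount
            egg water oil - substance
            stove - device)
  (:functions (is-at ?what - takeable) - location
              (at-person) - place
              (objects_taken) - number
              (is-open ?l - location) - boolean
              (is-on ?d - device) - boolean
              (shell-open ?p - pool) - boolean
              (contains ?c - container ?s - substance) - boolean
              (stirred ?c - container) - boolean
              (cleaned ?t - takeable) - boolean
              (can-pour ?f - thing ?s - substance) - boolean)
  (:init
    (= (is-at bowl) cupboard_tl)
    (= (is-at plate) cupboard_tl)
    (= (is-at frying_pan) cupboard_bl)
    (= (is-at oil_bottle) cupboard_bl)
    (= (at-person) counter_place)
    (= (objects_taken) 0)
    (= (is-open counter) true)
    (= (is-open sink) true)
    (= (is-open stove_top) true)
    (can-pour faucet water)
    (can-pour oil_bottle oil)
    (can-pour open_egg_shell egg)
  )
  (:action take
    :parameters (?what - takeable ?from - location)
    :precondition (and (= (is-at ?what) ?from)
                       (= (is-open ?from) true)
                       (< (objects_taken) 3))
    :effect (and (assign (is-at ?what) hands)
                 (increase (objects_taken) 1))
    :label "take-{what}-{from}")
  (:action take
    :parameters (?n - amount ?what - pool ?from - location)
    :precondition (and (= (is-open ?from) true)
                       (< (objects_taken) 3))
    :effect (increase (objects_taken) ?n)
    :label "take-{n}-{what}-{from}")
  (:action put
    :parameters (?what - takeable ?to - location)
    :precondition (and (= (is-at ?what) hands)
                       (= (is-open ?to) true))
    :effect (and (assign (is-at ?what) ?to)
                 (decrease (objects_taken) 1))
    :label "put-{what}-{to}")
  (:action put
    :parameters (?n - amount ?what - pool ?to - location)
    :precondition (and (= (is-open ?to) true)
                       (>= (objects_taken) ?n))
    :effect (decrease (objects_taken) ?n)
    :label "put-{n}-{what}-{to}")
  (:action open
    :parameters (?o - openable)
    :precondition (= (is-open ?o) false)
    :effect (assign (is-open ?o) true)
    :label "open-{o}")
  (:action open
    :parameters (?p - pool)
    :effect (assign (shell-open ?p) true)
    :label "open-{p}")
  (:action close
    :parameters (?o - openable)
    :precondition (= (is-open ?o) true)
    :effect (assign (is-open ?o) false)
    :label "close-{o}")
  (:action walk
    :parameters (?from - place ?to - place)
    :precondition (= (at-person) ?from)
    :effect (assign (at-person) ?to)
    :label "walk-{from}-{to}")
  (:action turn_on
    :parameters (?d - device)
    :precondition (= (is-on ?d) false)
    :effect (assign (is-on ?d) true)
    :label "turn_on-{d}")
  (:action turn_off
    :parameters (?d - device)
    :precondition (= (is-on ?d) true)
    :effect (assign (is-on ?d) false)
    :label "turn_off-{d}")
  (:action fill
    :parameters (?what - substance ?from - thing ?to - container)
    :precondition (= (can-pour ?from ?what) true)
    :effect (assign (contains ?to ?what) true)
    :label "fill-{what}-{from}-{to}")
  (:action clean
    :parameters (?t - takeable)
    :effect (assign (cleaned ?t) true)
    :label "clean-{t}")
  (:action stir
    :parameters (?c - container)
    :effect (assign (stirred ?c) true)
    :label "stir-{c}")
  (:action shake
    :parameters (?c - container)
    :effect (and)
    :label "shake-{c}")
  (:action other
    :parameters ()
    :effect (and)
    :label "other")
)
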