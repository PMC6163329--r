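; Toy brownie-baking domain.  11 action classes: open, close, take, put,
; walk, turn_on, fill, clean, stir, shake, other.
;
; Single objects have a location fluent (is-at); interchangeable egg
; shells are handled as a pool with integer multiplicity tokens in the
; label (take-1-egg_shell-egg_box).  A person holds at most 3 objects.
; Surfaces (counter, sink) are permanently "open"; cupboards, the fridge
; and the egg box must be opened before anything is taken from them.
(define (domain brownie)
  (:types thing location place amount substance device pool - object
          takeable source - thing
          container pourable - takeable
          openable - location)
  (:objects bowl baking_pan measuring_cup_s measuring_cup_l - container
            brownie_box oil_bottle butter_dish - pourable
            faucet open_egg_shell - source
            egg_shell empty_egg_shell - pool
            counter sink hands - location
            cupboard_tl cupboard_tr cupboard_br fridge egg_box - openable
            counter_place fridge_place - place
            1 2 - amount
            egg water oil brownie_mix butter - substance
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
    (= (is-at brownie_box) cupboard_tl)
    (= (is-at bowl) cupboard_tr)
    (= (is-at measuring_cup_s) cupboard_tr)
    (= (is-at measuring_cup_l) cupboard_tr)
    (= (is-at oil_bottle) cupboard_br)
    (= (is-at baking_pan) cupboard_br)
    (= (is-at butter_dish) fridge)
    (= (at-person) counter_place)
    (= (objects_taken) 0)
    (= (is-open counter) true)
    (= (is-open sink) true)
    (can-pour faucet water)
    (can-pour oil_bottle oil)
    (can-pour brownie_box brownie_mix)
    (can-pour butter_dish butter)
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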