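# Default English context trigger lexicon
# phrase|category|role|direction
# Distilled from the public NegEx/ConText trigger term lists.
# categories: negation, experiencer_other, historical, hypothetical
# roles: trigger, pseudo, termination

# --- negation triggers, forward ---
no|negation|trigger|forward
no sign of|negation|trigger|forward
no signs of|negation|trigger|forward
no evidence of|negation|trigger|forward
no evidence for|negation|trigger|forward
not|negation|trigger|forward
without|negation|trigger|forward
denies|negation|trigger|forward
denied|negation|trigger|forward
denying|negation|trigger|forward
negative for|negation|trigger|forward
never had|negation|trigger|forward
never developed|negation|trigger|forward
free of|negation|trigger|forward
absence of|negation|trigger|forward
absent|negation|trigger|forward
cannot see|negation|trigger|forward
checked for|negation|trigger|forward
declined|negation|trigger|forward
declines|negation|trigger|forward
fails to reveal|negation|trigger|forward
no abnormal|negation|trigger|forward
no cause of|negation|trigger|forward
no complaints of|negation|trigger|forward
no evidence to suggest|negation|trigger|forward
no findings of|negation|trigger|forward
no findings to indicate|negation|trigger|forward
no history of|negation|trigger|forward
no indication of|negation|trigger|forward
no mention of|negation|trigger|forward
no new evidence of|negation|trigger|forward
no suspicion of|negation|trigger|forward
no suggestion of|negation|trigger|forward
not demonstrate|negation|trigger|forward
not exhibit|negation|trigger|forward
not reveal|negation|trigger|forward
not appreciate|negation|trigger|forward
patient was not|negation|trigger|forward
rather than|negation|trigger|forward
resolved|negation|trigger|forward
rules out|negation|trigger|forward
rule out|negation|trigger|forward
ruled out|negation|trigger|forward
rules him out for|negation|trigger|forward
test for|negation|trigger|forward
to exclude|negation|trigger|forward
unremarkable for|negation|trigger|forward
with no|negation|trigger|forward
doubt|negation|trigger|forward
excluded|negation|trigger|forward

# --- negation triggers, backward ---
is ruled out|negation|trigger|backward
are ruled out|negation|trigger|backward
was ruled out|negation|trigger|backward
were ruled out|negation|trigger|backward
has been ruled out|negation|trigger|backward
have been ruled out|negation|trigger|backward
being ruled out|negation|trigger|backward
is excluded|negation|trigger|backward
was excluded|negation|trigger|backward
is not present|negation|trigger|backward
was not present|negation|trigger|backward
not seen|negation|trigger|backward
unlikely|negation|trigger|backward
was negative|negation|trigger|backward
is negative|negation|trigger|backward
free|negation|trigger|backward
was not found|negation|trigger|backward

# --- negation pseudo-triggers (suppress an embedded trigger) ---
no increase|negation|pseudo|forward
no change|negation|pseudo|forward
no further|negation|pseudo|forward
no significant change|negation|pseudo|forward
no interval change|negation|pseudo|forward
no suspicious change|negation|pseudo|forward
no definite change|negation|pseudo|forward
not extend|negation|pseudo|forward
not cause|negation|pseudo|forward
not certain if|negation|pseudo|forward
not certain whether|negation|pseudo|forward
not necessarily|negation|pseudo|forward
not rule out|negation|pseudo|forward
not ruled out|negation|pseudo|forward
not been ruled out|negation|pseudo|forward
without difficulty|negation|pseudo|forward
without further|negation|pseudo|forward
gram negative|negation|pseudo|backward
no drainage|negation|pseudo|forward

# --- experiencer (other than patient) triggers, forward ---
mother|experiencer_other|trigger|forward
mother's|experiencer_other|trigger|forward
father|experiencer_other|trigger|forward
father's|experiencer_other|trigger|forward
brother|experiencer_other|trigger|forward
sister|experiencer_other|trigger|forward
aunt|experiencer_other|trigger|forward
uncle|experiencer_other|trigger|forward
grandmother|experiencer_other|trigger|forward
grandfather|experiencer_other|trigger|forward
grandparent|experiencer_other|trigger|forward
wife|experiencer_other|trigger|forward
husband|experiencer_other|trigger|forward
son|experiencer_other|trigger|forward
daughter|experiencer_other|trigger|forward
cousin|experiencer_other|trigger|forward
sibling|experiencer_other|trigger|forward
family history of|experiencer_other|trigger|forward
family history|experiencer_other|trigger|forward
fam hx|experiencer_other|trigger|forward

# --- temporality: historical triggers, forward ---
history of|historical|trigger|forward
history|historical|trigger|forward
past history of|historical|trigger|forward
past medical history|historical|trigger|forward
previous|historical|trigger|forward
previously|historical|trigger|forward
prior|historical|trigger|forward
in the past|historical|trigger|backward
status post|historical|trigger|forward
several years ago|historical|trigger|backward
years ago|historical|trigger|backward
childhood|historical|trigger|forward
as a child|historical|trigger|backward

# --- temporality: historical pseudo-triggers ---
history of present illness|historical|pseudo|forward
history and physical|historical|pseudo|forward
poor history|historical|pseudo|forward
social history|historical|pseudo|forward
family history of|historical|pseudo|forward

# --- temporality: hypothetical triggers, forward ---
if|hypothetical|trigger|forward
if negative|hypothetical|pseudo|forward
should|hypothetical|trigger|forward
should there be|hypothetical|trigger|forward
return if|hypothetical|trigger|forward
come back if|hypothetical|trigger|forward
in case of|hypothetical|trigger|forward
in case|hypothetical|trigger|forward
watch for|hypothetical|trigger|forward
monitor for|hypothetical|trigger|forward
look for|hypothetical|trigger|forward
as needed for|hypothetical|trigger|forward
could be|hypothetical|trigger|forward
may develop|hypothetical|trigger|forward
risk of|hypothetical|trigger|forward
risk for|hypothetical|trigger|forward

# --- termination terms (close any open scope) ---
but|-|termination|-
however|-|termination|-
nevertheless|-|termination|-
yet|-|termination|-
though|-|termination|-
although|-|termination|-
still|-|termination|-
aside from|-|termination|-
apart from|-|termination|-
except|-|termination|-
other than|-|termination|-
secondary to|-|termination|-
as a cause of|-|termination|-
as a cause for|-|termination|-
as an etiology of|-|termination|-
which|-|termination|-
who|-|termination|-
presenting|-|termination|-
presents|-|termination|-
reports|-|termination|-
reported|-|termination|-
states|-|termination|-
complains of|-|termination|-
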