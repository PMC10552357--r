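# Negated / uncertain term constructions, one template per line.
# "{term}" marks the slot for the target term; "{term}?" matches a mention
# with an attached question mark. Tokens are matched after tokenization.
not {term}
no {term}
{term}?
rule out {term}
ruled out {term}
{term} ruled out
r/o {term}
denies {term}
denied {term}
denying {term}
without {term}
no evidence of {term}
no signs of {term}
no symptoms of {term}
no history of {term}
no hx of {term}
negative for {term}
neg for {term}
not yet {term}
never had {term}
absence of {term}
free of {term}
doubt {term}
doubtful {term}
unlikely {term}
{term} unlikely
{term} not present
{term} excluded
{term} not confirmed
exclude {term}
excluded {term}
possible {term}
possibly {term}
probable {term}
presumed {term}
suspected {term}
suspect {term}
query {term}
queried {term}
questionable {term}
likely {term}
consider {term}
considering {term}
{term} suspected
{term} possible
{term} in question
assess for {term}
evaluate for {term}
screen for {term}
versus {term}
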