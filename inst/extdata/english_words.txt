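# Minimal non-chemical English word list (lower case, one per line).
# Used by the curation filters (first-word test), entity extension
# boundaries, and as the filler-word pool of the synthetic corpus
# generator. Deliberately excludes words that double as chemical terms
# (element names, "lead", "gold", etc.).
a
able
about
above
across
action
active
activity
add
added
addition
additional
affect
affected
after
again
against
age
ago
all
almost
along
already
also
although
always
among
amount
an
analysis
and
animal
animals
another
answer
any
appear
approach
are
area
around
as
ask
assay
assess
assessed
assessment
associated
association
at
available
average
away
back
based
baseline
be
became
because
become
been
before
began
begin
behavior
being
below
benefit
best
better
between
beyond
both
brain
brief
bring
broad
but
by
came
can
cannot
case
cases
cause
caused
cell
cells
certain
change
changes
clear
clearly
clinical
cohort
come
command
common
commonly
compare
compared
comparison
complete
completely
complex
concentration
conclusion
condition
conditions
conduct
conducted
confirm
confirmed
consider
considered
consistent
contain
contained
containing
contains
context
continue
control
controls
could
course
culture
current
currently
data
day
days
decrease
decreased
define
defined
degree
demonstrate
demonstrated
describe
described
design
designed
despite
detail
detect
detected
detection
determine
determined
develop
developed
development
did
differ
difference
differences
different
difficult
direct
directly
discussion
disease
distinct
do
does
done
dose
down
drug
due
during
each
early
effect
effective
effects
eight
either
enhance
enhanced
enough
ensure
entire
especially
establish
established
estimate
estimated
evaluate
evaluated
evaluation
even
evidence
exact
examine
examined
example
except
experiment
experimental
experiments
explain
expression
extent
factor
factors
far
feature
features
few
field
finding
findings
first
five
focus
following
form
formed
found
four
frequency
frequent
from
full
function
functional
further
gave
general
generally
give
given
great
greater
group
groups
growth
had
has
have
having
health
healthy
held
help
here
high
higher
highly
host
hour
hours
how
however
human
humans
idea
identify
identified
if
important
improve
improved
improvement
in
include
included
includes
including
increase
increased
increasing
indeed
indicate
indicated
individual
induce
induced
effectively
influence
information
initial
into
investigate
investigated
involved
is
issue
it
its
itself
keep
key
kind
know
known
large
larger
last
late
later
least
leave
left
less
level
levels
light
like
likely
limit
limited
line
lines
little
local
long
longer
low
lower
made
main
mainly
major
make
making
many
may
mean
measure
measured
measurement
mechanism
method
methods
might
model
models
moderate
month
months
more
moreover
most
mostly
much
multiple
must
near
nearly
need
needed
neither
never
new
next
nine
no
none
normal
not
note
noted
novel
now
number
observation
observe
observed
obtain
obtained
occur
occurred
occurs
of
off
often
old
on
once
one
only
onto
optimizer
or
order
other
others
our
out
outcome
outcomes
over
overall
own
paper
part
particular
particularly
patient
patients
pattern
patterns
per
percent
performance
performed
perhaps
period
place
plan
point
points
poor
population
possible
potential
potentially
present
presented
previous
previously
primary
prior
problem
procedure
process
procure
produce
produced
profile
program
progress
promote
property
proposed
protocol
provide
provided
provides
purpose
question
random
range
rate
rates
rather
ratio
reach
reached
recent
recently
reduce
reduced
reduction
region
regions
related
relation
relative
relatively
release
relevant
remain
remained
remains
report
reported
represent
require
required
research
respect
response
responses
rest
result
resulted
results
review
right
risk
robust
role
same
sample
samples
saw
say
scale
score
scores
screen
screening
second
section
see
seen
select
selected
serum
set
seven
several
severe
severity
should
show
showed
shown
shows
side
significant
significantly
similar
similarly
simple
since
single
site
sites
six
size
small
smaller
so
some
something
sometimes
source
specific
specifically
stable
stage
standard
start
started
state
states
status
still
strain
strains
strong
strongly
study
studied
studies
subject
subjects
subsequent
subset
such
suggest
suggested
suggests
sum
summary
support
supported
surpass
surface
survey
system
systems
take
taken
target
targets
task
ten
term
terms
test
tested
testing
tests
than
that
the
their
them
then
there
therefore
these
they
third
this
those
three
through
throughout
thus
time
times
tissue
tissues
to
today
together
too
total
toward
treat
treated
treatment
trial
trials
two
type
types
under
understand
understood
unique
unknown
unless
until
up
upon
use
used
useful
using
usually
value
values
variable
variation
various
version
versus
very
via
view
was
way
we
week
weeks
well
were
what
when
where
whether
which
while
who
whole
whose
why
wide
widely
will
with
within
without
work
would
year
years
yet
yield
transferase
kinase
synthase
synthetase
dehydrogenase
oxidase
reductase
phosphatase
hydrolase
polymerase
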