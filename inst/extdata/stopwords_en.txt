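a
an
the
and
or
but
nor
so
yet
for
of
in
on
at
by
to
from
with
without
within
into
onto
about
above
below
under
over
between
among
through
during
before
after
since
until
up
down
out
off
again
further
then
once
here
there
where
when
why
how
what
which
who
whom
whose
that
this
these
those
is
am
are
was
were
be
been
being
have
has
had
having
do
does
did
doing
will
would
shall
should
can
could
may
might
must
not
no
i
me
my
mine
we
us
our
ours
you
your
yours
he
him
his
she
her
hers
it
its
they
them
their
theirs
as
if
than
because
while
such
both
each
few
more
most
other
some
any
all
only
own
same
too
very
just
also
s
t
don
now
ever
however
therefore
thus
hence
either
neither
whether
although
though
unless
per
via
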