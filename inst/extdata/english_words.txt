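about
above
after
again
almost
along
always
among
animal
answer
appear
apple
around
baker
basket
beach
began
begin
being
below
better
between
birds
black
bland
blank
bloom
board
boats
bread
break
bright
bring
broad
brown
build
built
calm
candle
carry
catch
cause
chance
change
charge
chart
check
cheese
chief
child
choice
clean
clear
climb
clock
close
cloth
cloud
coast
cold
color
common
cool
corn
corner
could
count
country
course
cover
craft
cream
crowd
crown
dance
dark
dear
decide
deep
degree
desert
design
dinner
direct
doctor
dollar
double
doubt
dream
dress
drink
drive
early
earth
eight
either
energy
enjoy
enough
enter
equal
evening
event
every
exact
example
except
expect
fair
fall
famous
fancy
farm
fast
favor
feel
fence
field
fight
figure
final
finish
fire
first
flat
floor
flower
follow
forest
forget
forward
found
frame
fresh
friend
front
fruit
full
funny
garden
gather
gentle
glass
globe
gold
good
grand
grass
great
green
ground
group
grow
guard
guess
guide
habit
hair
half
hand
happy
hard
heart
heavy
help
hill
hold
hollow
honey
hope
horse
hotel
hour
house
hundred
hurry
ice
idea
inch
iron
island
joy
judge
jump
just
keep
kind
king
kitchen
knee
knew
know
ladder
lake
land
large
last
laugh
lazy
lead
leaf
learn
leave
left
lemon
less
letter
level
life
light
line
lion
listen
little
live
local
long
look
loud
love
lucky
lunch
machine
made
magic
main
make
manner
many
march
mark
market
master
match
matter
maybe
meadow
meal
mean
measure
meet
melon
metal
middle
might
mile
milk
mind
mine
minute
mirror
modern
moment
money
month
moon
more
morning
most
mountain
mouse
mouth
move
much
music
must
name
near
neat
never
news
next
nice
night
noise
north
note
nothing
notice
number
ocean
offer
often
once
only
open
orange
order
other
over
page
paint
pair
paper
part
party
pass
past
peace
pencil
people
perfect
person
phone
piano
pick
picture
piece
place
plain
plan
plant
plate
play
please
plenty
point
pond
poor
popular
porch
pound
power
press
pretty
price
print
prize
proud
prove
pull
push
quick
quiet
quite
race
rain
raise
range
rapid
reach
read
ready
real
reason
record
remain
remember
rest
rich
ride
right
ring
rise
river
road
rock
roll
roof
room
rope
round
rule
safe
sail
salt
same
sand
save
scale
school
score
search
season
seat
second
secret
seem
sell
send
sense
serve
settle
seven
shade
shake
shall
shape
share
sharp
sheep
shelf
shine
ship
shirt
shoe
shop
shore
short
should
shout
show
side
sight
sign
silent
silver
simple
since
sing
sister
sixty
size
skill
sleep
slide
slow
small
smart
smile
smoke
smooth
snow
soft
some
song
soon
sort
sound
south
space
spare
speak
speed
spell
spend
spill
spoke
sport
spread
spring
square
stage
stand
star
start
state
station
stay
steel
step
stick
still
stone
store
storm
story
straight
strange
street
strong
study
such
sudden
sugar
summer
sunny
supper
sure
sweet
swim
table
take
talk
tall
taste
teach
team
tell
than
thank
that
their
there
these
thick
thin
thing
think
third
this
those
thought
three
through
throw
tide
tiger
time
tiny
today
together
told
tomorrow
tonight
tool
tooth
total
touch
toward
town
trade
train
travel
treat
tree
trick
trip
truck
true
trust
truth
turn
twelve
twenty
under
unit
until
upon
usual
valley
value
very
view
village
visit
voice
wait
walk
wall
want
warm
watch
water
wave
weak
wear
weather
week
well
west
what
wheel
when
where
which
while
white
whole
wide
wild
will
wind
window
winter
wise
wish
with
woman
wonder
wood
word
work
world
would
write
yard
year
yellow
young
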